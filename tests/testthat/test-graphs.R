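test_that("superpixel maps cover every pixel with contiguous labels", {
  img <- generate_center(phantom_config(n_benign = 1, n_malignant = 0,
                                        seed = 2))[[1]]$image
  sp <- slic_superpixels(img, target_segments = 120)
  expect_s3_class(sp, "superpixel_map")
  expect_identical(dim(sp$labels), dim(img))
  expect_true(all(sp$labels >= 1))
  expect_identical(sort(unique(as.vector(sp$labels))), seq_len(sp$n_segments))
  ## deterministic
  expect_identical(slic_superpixels(img, target_segments = 120), sp)
  ## every segment is 4-connected
  for (lab in seq_len(sp$n_segments)) {
    bw <- EBImage::bwlabel(sp$labels == lab)
    expect_equal(max(bw), 1)
  }
})

test_that("segment statistics average member pixels exactly", {
  img <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 0.5, 0.5, 0.5, 0.5), 3, 4)
  labels <- matrix(c(1L, 1L, 2L, 1L, 1L, 2L, 3L, 3L, 2L, 3L, 3L, 2L), 3, 4)
  sp <- structure(list(labels = labels, n_segments = 3L),
                  class = "superpixel_map")
  fm <- centroids_and_means(img, sp)
  for (lab in 1:3) {
    member <- which(labels == lab, arr.ind = TRUE)
    expect_equal(unname(fm[lab, "mean"]), mean(img[labels == lab]))
    expect_equal(unname(fm[lab, "centroid_row"]), mean(member[, 1]))
    expect_equal(unname(fm[lab, "centroid_col"]), mean(member[, 2]))
  }
})

test_that("the knn builder matches an exhaustive all-pairs search", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:30, 1)
    k <- sample(1:6, 1)
    pos <- matrix(runif(n * 2), n, 2)
    g <- build_knn_graph(pos, k)
    d <- as.matrix(stats::dist(pos))
    kk <- min(k, n - 1)
    for (v in seq_len(n)) {
      others <- setdiff(seq_len(n), v)
      want <- others[order(d[v, others], others)][seq_len(kk)]
      got <- g$edges[g$edges[, "src"] == v, "dst"]
      expect_identical(unname(got), want)
    }
    expect_equal(g$edge_attr, unname(d[g$edges]))
  }
})

test_that("distance ties break toward the lower node index", {
  ## four corners of a square: each node has two neighbours at distance 1
  pos <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  g <- build_knn_graph(pos, 1)
  expect_identical(unname(g$edges[, "dst"]), c(2L, 1L, 1L, 2L))
})

test_that("sixteen neighbours over 120 nodes give exactly 1920 directed edges", {
  set.seed(7)
  pos <- matrix(runif(240), 120, 2)
  g <- build_knn_graph(pos, 16)
  expect_identical(nrow(g$edges), 1920L)
})

test_that("a 32x32 phantom maps to a graph of around 120 nodes", {
  smp <- generate_center(phantom_config(n_benign = 2, n_malignant = 2, seed = 3))
  for (s in smp) {
    g <- image_to_graph(s$image, graph_config(), label = s$label)
    expect_s3_class(g, "lesion_graph")
    expect_gte(g$n_nodes, 110)
    expect_lte(g$n_nodes, 130)
    expect_identical(nrow(g$edges), g$n_nodes * 16L)
    expect_identical(ncol(g$node_features), 3L)
    expect_true(all(g$node_features[, c("row", "col")] >= 0 &
                      g$node_features[, c("row", "col")] <= 1))
    expect_true(all(g$edge_attr > 0))
  }
})

test_that("graphs survive a CSV round trip", {
  img <- generate_center(phantom_config(n_benign = 1, n_malignant = 0,
                                        seed = 6))[[1]]$image
  g <- image_to_graph(img, graph_config(target_segments = 40, k = 5),
                      label = 0L, sample_id = "s1")
  prefix <- tempfile("graph")
  write_graph_csv(g, prefix)
  back <- read_graph_csv(prefix, label = 0L)
  expect_identical(back$n_nodes, g$n_nodes)
  expect_identical(unname(back$edges), unname(g$edges))
  expect_equal(unname(back$node_features), unname(g$node_features),
               tolerance = 1e-12)
  expect_equal(back$edge_attr, g$edge_attr, tolerance = 1e-12)
  unlink(paste0(prefix, c("_nodes.csv", "_edges.csv")))
})

test_that("graphml output lists every node and edge", {
  set.seed(2)
  pos <- matrix(runif(20), 10, 2)
  kg <- build_knn_graph(pos, 3)
  g <- structure(list(node_features = cbind(mean = runif(10), row = pos[, 1],
                                            col = pos[, 2]),
                      edges = kg$edges, edge_attr = kg$edge_attr,
                      n_nodes = 10L, label = 1L, sample_id = "x"),
                 class = "lesion_graph")
  path <- tempfile(fileext = ".graphml")
  write_graphml(g, path)
  txt <- readLines(path)
  expect_identical(sum(grepl("<node ", txt)), 10L)
  expect_identical(sum(grepl("<edge ", txt)), 30L)
  expect_true(any(grepl("graphml.graphdrawing.org", txt)))
  unlink(path)
})
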
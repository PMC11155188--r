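## helpers to build tiny in-memory graphs without running segmentation
tiny_graph <- function(n, seed) {
  set.seed(seed)
  pos <- matrix(runif(n * 2), n, 2)
  kg <- build_knn_graph(pos, 2)
  structure(list(node_features = cbind(mean = runif(n), row = pos[, 1],
                                       col = pos[, 2]),
                 edges = kg$edges, edge_attr = kg$edge_attr, n_nodes = n,
                 label = NA_integer_, sample_id = NA_character_),
            class = "lesion_graph")
}

tiny_batch <- function(B, side, seed) {
  set.seed(seed)
  list(images = lapply(seq_len(B), function(i) matrix(runif(side^2), side, side)),
       graphs = lapply(seq_len(B), function(i) tiny_graph(5 + i, seed + i)),
       labels = rep_len(0:1, B))
}

test_that("convolution matches a direct sliding-window computation", {
  set.seed(1)
  for (case in list(list(stride = 1, pad = 1, kh = 3),
                    list(stride = 2, pad = 1, kh = 3),
                    list(stride = 2, pad = 0, kh = 1))) {
    H <- 6; W <- 6; Ci <- 3; Co <- 2; B <- 2
    x <- array(rnorm(H * W * B * Ci), c(H, W, B, Ci))
    Wt <- matrix(rnorm(case$kh^2 * Ci * Co), case$kh^2 * Ci, Co)
    b <- rnorm(Co)
    out <- fedhybrid:::conv2d_forward(x, Wt, b, case$stride, case$pad, case$kh)$out
    Ho <- (H + 2 * case$pad - case$kh) %/% case$stride + 1
    for (bi in seq_len(B)) for (co in seq_len(Co)) {
      for (i in seq_len(Ho)) for (j in seq_len(Ho)) {
        acc <- b[co]
        for (ci in seq_len(Ci)) for (dj in seq_len(case$kh)) for (di in seq_len(case$kh)) {
          r <- (i - 1) * case$stride + di - case$pad
          cc <- (j - 1) * case$stride + dj - case$pad
          xv <- if (r >= 1 && r <= H && cc >= 1 && cc <= W) x[r, cc, bi, ci] else 0
          wrow <- di + (dj - 1) * case$kh + (ci - 1) * case$kh^2
          acc <- acc + xv * Wt[wrow, co]
        }
        expect_equal(out[i, j, bi, co], acc, tolerance = 1e-12)
      }
    }
  }
})

test_that("training-mode batch normalisation standardises each channel", {
  set.seed(2)
  x <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  r <- fedhybrid:::bn1d_forward(x, gamma = rep(1, 4), beta = rep(0, 4),
                                rm = rep(0, 4), rv = rep(1, 4), train = TRUE)
  expect_equal(colMeans(r$out), rep(0, 4), tolerance = 1e-8)
  expect_equal(apply(r$out, 2, function(v) mean(v^2)), rep(1, 4),
               tolerance = 1e-3)
  ## running statistics move toward the batch statistics
  expect_equal(r$rm, 0.1 * colMeans(x), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  nc <- small_net(image_size = 12)
  params <- init_hybrid_params(nc, seed = 4)
  tb <- tiny_batch(3, 12, seed = 5)
  set.seed(55)
  f_glob <- matrix(rnorm(3 * (nc$image_feature_dim + nc$graph_feature_dim)), 3)
  loss_of <- function(p) {
    fw <- hybrid_forward(tb$images, tb$graphs, p, nc, train = FALSE)
    composite_loss(fw$logits, tb$labels, NULL, fw$fused, f_glob)$loss
  }
  fw <- hybrid_forward(tb$images, tb$graphs, params, nc, train = FALSE,
                       keep_cache = TRUE)
  ls <- composite_loss(fw$logits, tb$labels, NULL, fw$fused, f_glob)
  grads <- fedhybrid:::.fh_hybrid_backward(ls$dlogits, ls$dfused, fw$caches,
                                           params, nc)
  set.seed(6)
  blocks <- c("img.conv0.W", "img.s2.b1.conv1.W", "img.s2.b1.sc.W",
              "img.bnf.gamma", "gin.b1.msg.W", "gin.b2.fc1.W",
              "gin.refiner.fc2.W", "fuse.fc1.W", "fuse.fc2.b")
  eps <- 1e-5
  for (nm in blocks) {
    for (ix in sample(length(params[[nm]]), 2)) {
      p2 <- params
      p2[[nm]][ix] <- p2[[nm]][ix] + eps
      up <- loss_of(p2)
      p2[[nm]][ix] <- p2[[nm]][ix] - 2 * eps
      dn <- loss_of(p2)
      num <- (up - dn) / (2 * eps)
      ana <- grads[[nm]][ix]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("the graph branch is invariant to node relabelling", {
  nc <- small_net()
  params <- init_hybrid_params(nc, seed = 7)
  g <- tiny_graph(12, seed = 8)
  set.seed(9)
  p <- sample(12)
  pos <- integer(12); pos[p] <- seq_len(12)
  gp <- g
  gp$node_features <- g$node_features[p, ]
  gp$edges <- cbind(src = pos[g$edges[, "src"]], dst = pos[g$edges[, "dst"]])
  f1 <- graph_branch_forward(list(g), params, nc, train = FALSE)$feature
  f2 <- graph_branch_forward(list(gp), params, nc, train = FALSE)$feature
  expect_equal(f1, f2, tolerance = 1e-5)
})

test_that("zeroed residual branches propagate the stem features unchanged", {
  nc <- small_net()
  params <- init_hybrid_params(nc, seed = 10)
  params[["img.s1.b1.conv1.W"]][] <- 0
  params[["img.s1.b1.conv2.W"]][] <- 0
  tb <- tiny_batch(2, 32, seed = 11)
  fw <- image_branch_forward(tb$images, params, nc, train = FALSE)
  x <- fedhybrid:::.fh_stack_images(tb$images)
  stem <- fedhybrid:::conv2d_forward(x, params[["img.conv0.W"]],
                                     params[["img.conv0.b"]], 1, 1, 3)$out
  expect_equal(fw$cache$stage_out[[1]], stem, tolerance = 1e-12)
})

test_that("evaluation-mode forwards are batch-independent", {
  nc <- small_net()
  params <- init_hybrid_params(nc, seed = 12)
  tb <- tiny_batch(3, 32, seed = 13)
  all3 <- hybrid_forward(tb$images, tb$graphs, params, nc, train = FALSE)
  for (i in 1:3) {
    one <- hybrid_forward(tb$images[i], tb$graphs[i], params, nc, train = FALSE)
    expect_equal(unname(one$fused[1, ]), unname(all3$fused[i, ]),
                 tolerance = 1e-10)
    expect_equal(one$prob, all3$prob[i], tolerance = 1e-10)
  }
})

test_that("graph batching block-diagonalises edges with correct offsets", {
  g1 <- tiny_graph(4, seed = 14)
  g2 <- tiny_graph(6, seed = 15)
  bg <- batch_graphs(list(g1, g2))
  expect_identical(nrow(bg$X), 10L)
  expect_identical(bg$graph_id, rep(1:2, c(4L, 6L)))
  expect_identical(unname(bg$edges[seq_len(nrow(g1$edges)), ]),
                   unname(g1$edges))
  expect_identical(unname(bg$edges[-seq_len(nrow(g1$edges)), ]),
                   unname(g2$edges + 4L))
})

test_that("checkpoints round-trip parameter lists exactly", {
  nc <- small_net()
  params <- init_hybrid_params(nc, seed = 16)
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(params, path)
  back <- load_checkpoint(path)
  expect_identical(names(back), names(params))
  for (nm in names(params)) expect_equal(back[[nm]], params[[nm]])
  unlink(path)
})

test_that("a few epochs of gradient descent reduce the training loss", {
  prep <- small_prepared()
  cfg <- fed_config(local_epochs = 2, communication_rounds = 2,
                    finetune_epochs = 0, batch_size = 8,
                    use_prev_term = FALSE, use_global_term = FALSE, seed = 17)
  res <- centralized_train(prep, small_net(), cfg, center_id = "t")
  lh <- res$client$loss_history
  expect_length(lh, 4)
  expect_lt(lh[length(lh)], lh[1])
})
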
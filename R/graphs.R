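#' Graph-construction configuration
#'
#' @param target_segments Requested superpixel count (default 120, tuned so a
#'   32x32 image yields about 120 nodes).
#' @param k Neighbours per node in the KNN graph (default 16; with ~120 nodes
#'   this gives ~1920 directed edges).
#' @param compactness SLIC intensity/space balance (default 0.2).
#' @param normalize_distances Divide edge attributes by their maximum
#'   (default FALSE: raw pixel distances).
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(target_segments = 120, k = 16, compactness = 0.2,
                         normalize_distances = FALSE) {
  if (k < 1) fh_stop("k must be >= 1", "fh_invalid_config")
  structure(list(target_segments = as.integer(target_segments),
                 k = as.integer(k), compactness = compactness,
                 normalize_distances = isTRUE(normalize_distances)),
            class = "graph_config")
}

#' Per-segment mean intensity and centroid
#'
#' @param image Numeric matrix.
#' @param spmap A `superpixel_map` of the same shape.
#' @return An `n_segments x 3` matrix with columns `mean`, `centroid_row`,
#'   `centroid_col` (1-based pixel coordinates, arithmetic mean of member
#'   pixel coordinates).
#' @export
centroids_and_means <- function(image, spmap) {
  if (!all(dim(image) == dim(spmap$labels))) {
    fh_stop("image and superpixel map shapes disagree", "fh_invalid_input")
  }
  h <- nrow(image)
  lv <- as.vector(spmap$labels)
  n <- spmap$n_segments
  cnt <- tabulate(lv, nbins = n)
  if (any(cnt == 0)) fh_stop("empty superpixel segment", "fh_internal")
  idx <- seq_along(lv)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  out <- cbind(mean = as.vector(rowsum(as.vector(image), lv)) / cnt,
               centroid_row = as.vector(rowsum(rr, lv)) / cnt,
               centroid_col = as.vector(rowsum(cc, lv)) / cnt)
  out
}

#' Directed K-nearest-neighbour graph over node positions
#'
#' Each node emits directed edges to its `k` nearest other nodes by Euclidean
#' distance (to all others if fewer than `k` exist); distance ties are broken
#' toward the lower node index. The edge attribute is the distance itself.
#'
#' @param positions Numeric matrix, one row per node (any dimensionality).
#' @param k Neighbours per node (>= 1).
#' @return List with `edges` (integer matrix, columns `src`, `dst`) and
#'   `edge_attr` (numeric vector of Euclidean distances, one per edge).
#' @export
build_knn_graph <- function(positions, k) {
  n <- nrow(positions)
  if (is.null(n) || n < 2) fh_stop("need at least 2 nodes", "fh_invalid_input")
  if (k < 1) fh_stop("k must be >= 1", "fh_invalid_config")
  d <- as.matrix(stats::dist(positions))
  kk <- min(k, n - 1)
  src <- integer(0); dst <- integer(0); att <- numeric(0)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    ord <- others[order(d[v, others], others)][seq_len(kk)]
    src <- c(src, rep.int(v, kk))
    dst <- c(dst, ord)
    att <- c(att, d[v, ord])
  }
  list(edges = cbind(src = src, dst = dst), edge_attr = unname(att))
}

#' Convert one image into a lesion graph
#'
#' Composition of the unsupervised image-to-graph path: SLIC superpixel
#' segmentation, per-segment mean intensity and centroid, then a directed
#' KNN graph over centroids with Euclidean-distance edge attributes. Node
#' features are `[mean intensity, centroid row, centroid col]` with the
#' centroid coordinates mapped into `[0, 1]` (divided by `side - 1`) so
#' intensity and position share scale.
#'
#' @param image Numeric matrix (typically the resized 32x32,
#'   pre-augmentation image).
#' @param config A [graph_config()].
#' @param label Optional class label (0/1) carried on the graph.
#' @param sample_id Optional identifier carried on the graph.
#' @return An object of class `lesion_graph`: list with `node_features`
#'   (n x 3), `edges`, `edge_attr`, `n_nodes`, `label`, `sample_id`.
#' @export
#' @examples
#' img <- generate_center(phantom_config(n_benign = 1, n_malignant = 0))[[1]]
#' g <- image_to_graph(img$image, graph_config(), label = img$label)
#' g$n_nodes
image_to_graph <- function(image, config = graph_config(), label = NA_integer_,
                           sample_id = NA_character_) {
  spmap <- slic_superpixels(image, target_segments = config$target_segments,
                            compactness = config$compactness)
  feats <- centroids_and_means(image, spmap)
  kg <- build_knn_graph(feats[, c("centroid_row", "centroid_col")], config$k)
  attr_out <- kg$edge_attr
  if (config$normalize_distances && max(attr_out) > 0) {
    attr_out <- attr_out / max(attr_out)
  }
  nf <- cbind(mean = feats[, "mean"],
              row = (feats[, "centroid_row"] - 1) / (nrow(image) - 1),
              col = (feats[, "centroid_col"] - 1) / (ncol(image) - 1))
  structure(list(node_features = nf, edges = kg$edges, edge_attr = attr_out,
                 n_nodes = spmap$n_segments, label = label,
                 sample_id = sample_id),
            class = "lesion_graph")
}

#' Serialize a lesion graph to node/edge CSV files
#'
#' @param graph A `lesion_graph`.
#' @param prefix Path prefix; writes `<prefix>_nodes.csv` and
#'   `<prefix>_edges.csv`.
#' @return Invisibly, the two file paths.
#' @export
write_graph_csv <- function(graph, prefix) {
  nodes <- data.frame(node = seq_len(graph$n_nodes), graph$node_features)
  edges <- data.frame(src = graph$edges[, "src"], dst = graph$edges[, "dst"],
                      dist = graph$edge_attr)
  np <- paste0(prefix, "_nodes.csv"); ep <- paste0(prefix, "_edges.csv")
  utils::write.csv(nodes, np, row.names = FALSE)
  utils::write.csv(edges, ep, row.names = FALSE)
  invisible(c(np, ep))
}

#' Read a lesion graph back from CSV files written by [write_graph_csv()]
#' @param prefix Path prefix used when writing.
#' @param label Optional label to attach.
#' @return A `lesion_graph`.
#' @export
read_graph_csv <- function(prefix, label = NA_integer_) {
  nodes <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  edges <- utils::read.csv(paste0(prefix, "_edges.csv"))
  structure(list(node_features = as.matrix(nodes[, c("mean", "row", "col")]),
                 edges = cbind(src = edges$src, dst = edges$dst),
                 edge_attr = edges$dist, n_nodes = nrow(nodes),
                 label = label, sample_id = NA_character_),
            class = "lesion_graph")
}

#' Write a lesion graph in GraphML format
#'
#' @param graph A `lesion_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="mean" for="node" attr.name="mean" attr.type="double"/>')
  w('  <key id="row" for="node" attr.name="row" attr.type="double"/>')
  w('  <key id="col" for="node" attr.name="col" attr.type="double"/>')
  w('  <key id="dist" for="edge" attr.name="dist" attr.type="double"/>')
  w('  <graph id="G" edgedefault="directed">')
  for (i in seq_len(graph$n_nodes)) {
    w(sprintf('    <node id="n%d"><data key="mean">%.10g</data><data key="row">%.10g</data><data key="col">%.10g</data></node>',
              i, graph$node_features[i, 1], graph$node_features[i, 2],
              graph$node_features[i, 3]))
  }
  for (e in seq_along(graph$edge_attr)) {
    w(sprintf('    <edge source="n%d" target="n%d"><data key="dist">%.10g</data></edge>',
              graph$edges[e, "src"], graph$edges[e, "dst"], graph$edge_attr[e]))
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}
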
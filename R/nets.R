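#' Hybrid two-branch network configuration
#'
#' The classifier has an image branch (pre-activation residual network: three
#' stages of basic blocks, each block two 3x3 convolutions on a
#' batch-norm -> ReLU -> convolution ordering, with identity skip
#' connections), a graph branch (four edge-aware graph-isomorphism blocks,
#' each a message step over in-neighbours followed by fully connected layers,
#' then sum pooling and a dropout MLP refiner), and a fusion MLP over the
#' concatenated branch features.
#'
#' @param image_depth Residual depth; `(depth - 2)` must be divisible by 6.
#'   The reference depth is 110 (18 blocks per stage); the package default is
#'   the desk-scale 20 (3 blocks per stage). Architecture is identical at any
#'   depth.
#' @param base_width Channels of the first stage (stages use
#'   `base_width * c(1, 2, 4)`); default 8, so the image feature has length
#'   32. The default is sized for single-CPU training on the synthetic
#'   phantom study; widen for real datasets.
#' @param image_size Input side in pixels (default 32).
#' @param gin_blocks Number of graph blocks (default 4).
#' @param graph_hidden Width of the graph-block MLPs and refiner (default 32,
#'   sized like `base_width` for single-CPU training).
#' @param node_feature_dim Node-feature length (default 3: mean intensity,
#'   centroid row, centroid col).
#' @param fusion_hidden Width of the fusion MLP hidden layer (default 64).
#' @param dropout_rate Refiner dropout probability (default 0.5).
#' @param readout Graph pooling, `"mean"` (default; keeps the pooled feature
#'   scale independent of node count, which is needed for stable optimisation
#'   at this scale) or `"sum"` (GIN-canonical).
#' @param n_classes Number of classes (2).
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(image_depth = 20, base_width = 8, image_size = 32,
                          gin_blocks = 4, graph_hidden = 32,
                          node_feature_dim = 3, fusion_hidden = 64,
                          dropout_rate = 0.5, readout = c("mean", "sum"),
                          n_classes = 2) {
  if ((image_depth - 2) %% 6 != 0) {
    fh_stop("(image_depth - 2) must be divisible by 6", "fh_invalid_config")
  }
  readout <- match.arg(readout)
  structure(list(image_depth = as.integer(image_depth),
                 blocks_per_stage = as.integer((image_depth - 2) / 6),
                 base_width = as.integer(base_width),
                 image_feature_dim = as.integer(4 * base_width),
                 image_size = as.integer(image_size),
                 gin_blocks = as.integer(gin_blocks),
                 graph_hidden = as.integer(graph_hidden),
                 graph_feature_dim = as.integer(graph_hidden),
                 node_feature_dim = as.integer(node_feature_dim),
                 fusion_hidden = as.integer(fusion_hidden),
                 dropout_rate = dropout_rate, readout = readout,
                 n_classes = as.integer(n_classes)),
            class = "hybrid_config")
}

.fh_he_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

#' Initialise hybrid-network parameters
#'
#' He-normal weights, zero biases, unit batch-norm scale. Batch-norm running
#' statistics are stored alongside the weights so the whole model state is
#' one flat named list (the unit of federated exchange).
#'
#' @param config A [hybrid_config()].
#' @param seed Integer seed.
#' @return Flat named list of numeric arrays.
#' @export
init_hybrid_params <- function(config, seed = 1) {
  set.seed(derive_seed(seed, "init"))
  p <- list()
  w <- config$base_width
  widths <- w * c(1, 2, 4)
  p[["img.conv0.W"]] <- .fh_he_mat(9 * 1, w)
  p[["img.conv0.b"]] <- numeric(w)
  cin <- w
  for (s in 1:3) {
    cout <- widths[s]
    for (u in seq_len(config$blocks_per_stage)) {
      pre <- sprintf("img.s%d.b%d.", s, u)
      p[[paste0(pre, "bn1.gamma")]] <- rep(1, cin)
      p[[paste0(pre, "bn1.beta")]] <- numeric(cin)
      p[[paste0(pre, "bn1.rm")]] <- numeric(cin)
      p[[paste0(pre, "bn1.rv")]] <- rep(1, cin)
      p[[paste0(pre, "conv1.W")]] <- .fh_he_mat(9 * cin, cout)
      p[[paste0(pre, "conv1.b")]] <- numeric(cout)
      p[[paste0(pre, "bn2.gamma")]] <- rep(1, cout)
      p[[paste0(pre, "bn2.beta")]] <- numeric(cout)
      p[[paste0(pre, "bn2.rm")]] <- numeric(cout)
      p[[paste0(pre, "bn2.rv")]] <- rep(1, cout)
      p[[paste0(pre, "conv2.W")]] <- .fh_he_mat(9 * cout, cout)
      p[[paste0(pre, "conv2.b")]] <- numeric(cout)
      if (cin != cout) {
        p[[paste0(pre, "sc.W")]] <- .fh_he_mat(cin, cout)
        p[[paste0(pre, "sc.b")]] <- numeric(cout)
      }
      cin <- cout
    }
  }
  p[["img.bnf.gamma"]] <- rep(1, cin)
  p[["img.bnf.beta"]] <- numeric(cin)
  p[["img.bnf.rm"]] <- numeric(cin)
  p[["img.bnf.rv"]] <- rep(1, cin)

  din <- config$node_feature_dim
  hid <- config$graph_hidden
  for (j in seq_len(config$gin_blocks)) {
    pre <- sprintf("gin.b%d.", j)
    p[[paste0(pre, "msg.W")]] <- .fh_he_mat(din + 1, din)
    p[[paste0(pre, "msg.b")]] <- numeric(din)
    p[[paste0(pre, "fc1.W")]] <- .fh_he_mat(din, hid)
    p[[paste0(pre, "fc1.b")]] <- numeric(hid)
    p[[paste0(pre, "bn1.gamma")]] <- rep(1, hid)
    p[[paste0(pre, "bn1.beta")]] <- numeric(hid)
    p[[paste0(pre, "bn1.rm")]] <- numeric(hid)
    p[[paste0(pre, "bn1.rv")]] <- rep(1, hid)
    p[[paste0(pre, "fc2.W")]] <- .fh_he_mat(hid, hid)
    p[[paste0(pre, "fc2.b")]] <- numeric(hid)
    p[[paste0(pre, "bn2.gamma")]] <- rep(1, hid)
    p[[paste0(pre, "bn2.beta")]] <- numeric(hid)
    p[[paste0(pre, "bn2.rm")]] <- numeric(hid)
    p[[paste0(pre, "bn2.rv")]] <- rep(1, hid)
    din <- hid
  }
  p[["gin.refiner.fc1.W"]] <- .fh_he_mat(hid, hid)
  p[["gin.refiner.fc1.b"]] <- numeric(hid)
  p[["gin.refiner.fc2.W"]] <- .fh_he_mat(hid, config$graph_feature_dim)
  p[["gin.refiner.fc2.b"]] <- numeric(config$graph_feature_dim)

  fin <- config$image_feature_dim + config$graph_feature_dim
  p[["fuse.fc1.W"]] <- .fh_he_mat(fin, config$fusion_hidden)
  p[["fuse.fc1.b"]] <- numeric(config$fusion_hidden)
  p[["fuse.fc2.W"]] <- .fh_he_mat(config$fusion_hidden, config$n_classes)
  p[["fuse.fc2.b"]] <- numeric(config$n_classes)
  p
}

## stack a list of images (H x W matrices) into [H, W, B, 1]
.fh_stack_images <- function(images) {
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  array(unlist(images, use.names = FALSE), c(h, w, length(images), 1))
}

#' Image-branch forward pass (pre-activation residual network)
#'
#' @param images List of H x W matrices, or an `[H, W, B, 1]` array.
#' @param params Parameter list from [init_hybrid_params()].
#' @param config A [hybrid_config()].
#' @param train Training mode (batch statistics) or evaluation mode (running
#'   statistics).
#' @param keep_cache Keep layer caches for backpropagation.
#' @return List with `feature` (B x image_feature_dim matrix), `cache`, and
#'   `bn_updates` (new running statistics when `train = TRUE`).
#' @export
image_branch_forward <- function(images, params, config, train = FALSE,
                                 keep_cache = FALSE) {
  x <- if (is.list(images)) .fh_stack_images(images) else images
  if (length(dim(x)) != 4 || dim(x)[1] != config$image_size ||
      dim(x)[2] != config$image_size) {
    fh_stop("image shape does not match config$image_size", "fh_invalid_input")
  }
  caches <- list(); bn_up <- list()
  bn <- function(name, xx) {
    r <- bn2d_forward(xx, params[[paste0(name, ".gamma")]],
                      params[[paste0(name, ".beta")]],
                      params[[paste0(name, ".rm")]],
                      params[[paste0(name, ".rv")]], train)
    if (train) bn_up[[name]] <<- list(rm = r$rm, rv = r$rv)
    caches[[name]] <<- r$cache
    r$out
  }
  cv <- function(name, xx, stride, pad, kh) {
    r <- conv2d_forward(xx, params[[paste0(name, ".W")]],
                        params[[paste0(name, ".b")]], stride, pad, kh)
    caches[[name]] <<- r$cache
    r$out
  }
  rl <- function(name, xx) {
    r <- relu_forward(xx)
    caches[[name]] <<- r$cache
    r$out
  }
  h <- cv("img.conv0", x, 1, 1, 3)
  stage_out <- list()
  for (s in 1:3) {
    for (u in seq_len(config$blocks_per_stage)) {
      pre <- sprintf("img.s%d.b%d.", s, u)
      stride <- if (s > 1 && u == 1) 2L else 1L
      a1 <- rl(paste0(pre, "a1"), bn(paste0(pre, "bn1"), h))
      shortcut <- if (!is.null(params[[paste0(pre, "sc.W")]])) {
        cv(paste0(pre, "sc"), a1, stride, 0, 1)
      } else h
      hh <- cv(paste0(pre, "conv1"), a1, stride, 1, 3)
      a2 <- rl(paste0(pre, "a2"), bn(paste0(pre, "bn2"), hh))
      hh <- cv(paste0(pre, "conv2"), a2, 1, 1, 3)
      h <- shortcut + hh
      caches[[paste0(pre, "has_sc")]] <- !is.null(params[[paste0(pre, "sc.W")]])
    }
    stage_out[[s]] <- h
  }
  af <- rl("img.af", bn("img.bnf", h))
  caches[["img.gap_dim"]] <- dim(af)
  feature <- gap_forward(af)
  list(feature = feature,
       cache = if (keep_cache) c(caches, list(stage_out = stage_out)) else list(stage_out = stage_out),
       bn_updates = bn_up)
}

## backward through the image branch; dfeat is B x D
.fh_image_branch_backward <- function(dfeat, caches, params, config) {
  g <- list()
  bnb <- function(name, dd) {
    r <- bn2d_backward(dd, caches[[name]])
    g[[paste0(name, ".gamma")]] <<- r$dgamma
    g[[paste0(name, ".beta")]] <<- r$dbeta
    r$dx
  }
  cvb <- function(name, dd) {
    r <- conv2d_backward(dd, caches[[name]])
    g[[paste0(name, ".W")]] <<- r$dW
    g[[paste0(name, ".b")]] <<- r$db
    r$dx
  }
  dh <- bnb("img.bnf", relu_backward(gap_backward(dfeat, caches[["img.gap_dim"]]),
                                     caches[["img.af"]]))
  for (s in 3:1) {
    for (u in rev(seq_len(config$blocks_per_stage))) {
      pre <- sprintf("img.s%d.b%d.", s, u)
      da2 <- cvb(paste0(pre, "conv2"), dh)
      dhh <- bnb(paste0(pre, "bn2"), relu_backward(da2, caches[[paste0(pre, "a2")]]))
      da1 <- cvb(paste0(pre, "conv1"), dhh)
      if (caches[[paste0(pre, "has_sc")]]) {
        da1 <- da1 + cvb(paste0(pre, "sc"), dh)
        dprev <- 0
      } else {
        dprev <- dh
      }
      dh <- dprev + bnb(paste0(pre, "bn1"),
                        relu_backward(da1, caches[[paste0(pre, "a1")]]))
    }
  }
  g[["img.conv0.W"]] <- NULL  # placeholder, set below
  r <- conv2d_backward(dh, caches[["img.conv0"]])
  g[["img.conv0.W"]] <- r$dW
  g[["img.conv0.b"]] <- r$db
  g
}

#' Batch a list of lesion graphs into one block-diagonal graph
#'
#' @param graphs List of `lesion_graph` objects.
#' @return List with stacked node features `X`, global-index `edges`,
#'   `edge_attr`, `graph_id` per node, and `n_graphs`.
#' @export
batch_graphs <- function(graphs) {
  nn <- vapply(graphs, function(g) as.integer(g$n_nodes), integer(1))
  offs <- cumsum(c(0L, nn))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edges
    if (is.null(e) || nrow(e) == 0) return(NULL)
    e + offs[i]
  }))
  eattr <- unlist(lapply(graphs, `[[`, "edge_attr"), use.names = FALSE)
  gid <- rep(seq_along(graphs), nn)
  list(X = X, edges = edges, edge_attr = eattr, graph_id = gid,
       n_graphs = length(graphs))
}

## sum rows of M into N bins given by idx; absent bins contribute zero rows
.fh_scatter_sum <- function(M, idx, N) {
  rs <- rowsum(M, idx)
  out <- matrix(0, N, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Graph-branch forward pass (edge-aware graph isomorphism network)
#'
#' Four graph blocks. In each block every directed edge `u -> v` builds a
#' message from the concatenation of the source-node state and the edge
#' attribute through a linear + ReLU map; messages are summed over the
#' in-neighbourhood `N(v)` (the empty neighbourhood contributes the zero
#' element), combined additively with the node's own state, and passed
#' through two fully connected layers. Node states are then pooled per graph
#' (sum by default) and refined by a dropout MLP.
#'
#' @param graphs List of `lesion_graph`s, or a pre-batched graph from
#'   [batch_graphs()].
#' @param params,config,train,keep_cache As in [image_branch_forward()].
#' @return List with `feature` (n_graphs x graph_feature_dim) and `cache`.
#' @export
graph_branch_forward <- function(graphs, params, config, train = FALSE,
                                 keep_cache = FALSE) {
  bg <- if (!is.null(graphs$X)) graphs else batch_graphs(graphs)
  if (is.null(bg$X) || nrow(bg$X) == 0) {
    fh_stop("graph has no nodes", "fh_invalid_input")
  }
  N <- nrow(bg$X)
  H <- bg$X
  caches <- list(bg = bg)
  bn_up <- list()
  bn <- function(name, xx) {
    r <- bn1d_forward(xx, params[[paste0(name, ".gamma")]],
                      params[[paste0(name, ".beta")]],
                      params[[paste0(name, ".rm")]],
                      params[[paste0(name, ".rv")]], train)
    if (train) bn_up[[name]] <<- list(rm = r$rm, rv = r$rv)
    caches[[name]] <<- r$cache
    r$out
  }
  for (j in seq_len(config$gin_blocks)) {
    pre <- sprintf("gin.b%d.", j)
    d <- ncol(H)
    if (!is.null(bg$edges) && nrow(bg$edges) > 0) {
      ## message linear over concat(h_src, edge_attr), computed blockwise so
      ## the 31k-row concatenated matrix is never materialised
      Wm <- params[[paste0(pre, "msg.W")]]
      hsrc <- H[bg$edges[, 1], , drop = FALSE]
      lm_out <- hsrc %*% Wm[seq_len(d), , drop = FALSE] +
        tcrossprod(bg$edge_attr, Wm[d + 1L, ])
      lm_out <- lm_out + rep(params[[paste0(pre, "msg.b")]],
                             each = nrow(lm_out))
      rm_ <- relu_forward(lm_out)
      agg <- .fh_scatter_sum(rm_$out, bg$edges[, 2], N)
      caches[[paste0(pre, "msg_lin")]] <- list(hsrc = hsrc, W = Wm)
      caches[[paste0(pre, "msg_relu")]] <- rm_$cache
    } else {
      agg <- matrix(0, N, d)
    }
    z <- H + agg
    l1 <- linear_forward(z, params[[paste0(pre, "fc1.W")]],
                         params[[paste0(pre, "fc1.b")]])
    r1 <- relu_forward(bn(paste0(pre, "bn1"), l1$out))
    l2 <- linear_forward(r1$out, params[[paste0(pre, "fc2.W")]],
                         params[[paste0(pre, "fc2.b")]])
    r2 <- relu_forward(bn(paste0(pre, "bn2"), l2$out))
    caches[[paste0(pre, "fc1")]] <- l1$cache
    caches[[paste0(pre, "r1")]] <- r1$cache
    caches[[paste0(pre, "fc2")]] <- l2$cache
    caches[[paste0(pre, "r2")]] <- r2$cache
    H <- r2$out
  }
  pooled <- .fh_scatter_sum(H, bg$graph_id, bg$n_graphs)
  if (config$readout == "mean") {
    cnt <- tabulate(bg$graph_id, nbins = bg$n_graphs)
    pooled <- pooled / cnt
    caches[["pool_cnt"]] <- cnt
  }
  l1 <- linear_forward(pooled, params[["gin.refiner.fc1.W"]],
                       params[["gin.refiner.fc1.b"]])
  r1 <- relu_forward(l1$out)
  dp <- dropout_forward(r1$out, config$dropout_rate, train)
  l2 <- linear_forward(dp$out, params[["gin.refiner.fc2.W"]],
                       params[["gin.refiner.fc2.b"]])
  r2 <- relu_forward(l2$out)
  caches[["ref.fc1"]] <- l1$cache; caches[["ref.r1"]] <- r1$cache
  caches[["ref.dp"]] <- dp$cache; caches[["ref.fc2"]] <- l2$cache
  caches[["ref.r2"]] <- r2$cache
  list(feature = r2$out, cache = if (keep_cache) caches else NULL,
       bn_updates = bn_up)
}

.fh_graph_branch_backward <- function(dfeat, caches, params, config) {
  g <- list()
  bg <- caches$bg
  N <- nrow(bg$X)
  linb <- function(name, dd) {
    r <- linear_backward(dd, caches[[name]])
    g[[paste0(sub("^ref\\.", "gin.refiner.", name), ".W")]] <<- r$dW
    g[[paste0(sub("^ref\\.", "gin.refiner.", name), ".b")]] <<- r$db
    r$dx
  }
  dd <- relu_backward(dfeat, caches[["ref.r2"]])
  dd <- linb("ref.fc2", dd)
  dd <- dropout_backward(dd, caches[["ref.dp"]])
  dd <- relu_backward(dd, caches[["ref.r1"]])
  dpooled <- linb("ref.fc1", dd)
  if (config$readout == "mean") dpooled <- dpooled / caches[["pool_cnt"]]
  dH <- dpooled[bg$graph_id, , drop = FALSE]
  for (j in rev(seq_len(config$gin_blocks))) {
    pre <- sprintf("gin.b%d.", j)
    dd <- relu_backward(dH, caches[[paste0(pre, "r2")]])
    rb <- bn1d_backward(dd, caches[[paste0(pre, "bn2")]])
    g[[paste0(pre, "bn2.gamma")]] <- rb$dgamma
    g[[paste0(pre, "bn2.beta")]] <- rb$dbeta
    r <- linear_backward(rb$dx, caches[[paste0(pre, "fc2")]])
    g[[paste0(pre, "fc2.W")]] <- r$dW; g[[paste0(pre, "fc2.b")]] <- r$db
    dd <- relu_backward(r$dx, caches[[paste0(pre, "r1")]])
    rb <- bn1d_backward(dd, caches[[paste0(pre, "bn1")]])
    g[[paste0(pre, "bn1.gamma")]] <- rb$dgamma
    g[[paste0(pre, "bn1.beta")]] <- rb$dbeta
    r <- linear_backward(rb$dx, caches[[paste0(pre, "fc1")]])
    g[[paste0(pre, "fc1.W")]] <- r$dW; g[[paste0(pre, "fc1.b")]] <- r$db
    dz <- r$dx
    dH <- dz  # identity path of COMBINE
    if (!is.null(caches[[paste0(pre, "msg_lin")]])) {
      dM <- dz[bg$edges[, 2], , drop = FALSE]
      dM <- relu_backward(dM, caches[[paste0(pre, "msg_relu")]])
      mc <- caches[[paste0(pre, "msg_lin")]]
      d_in <- ncol(mc$hsrc)
      dW <- rbind(crossprod(mc$hsrc, dM), colSums(dM * bg$edge_attr))
      g[[paste0(pre, "msg.W")]] <- dW
      g[[paste0(pre, "msg.b")]] <- colSums(dM)
      dsrc <- tcrossprod(dM, mc$W[seq_len(d_in), , drop = FALSE])
      dH <- dH + .fh_scatter_sum(dsrc, bg$edges[, 1], N)
    } else {
      g[[paste0(pre, "msg.W")]] <- 0 * params[[paste0(pre, "msg.W")]]
      g[[paste0(pre, "msg.b")]] <- 0 * params[[paste0(pre, "msg.b")]]
    }
  }
  g
}

#' Fuse branch features and classify
#'
#' Concatenates image and graph features and applies the fusion MLP. The
#' softmax of the returned logits defines the malignancy probability
#' (class 1, the second logit).
#'
#' @param image_feature B x image_feature_dim matrix.
#' @param graph_feature B x graph_feature_dim matrix.
#' @param params,config,keep_cache As in [image_branch_forward()].
#' @return List with `logits` (B x 2), `fused` (the concatenated pre-fusion
#'   feature), and `cache`.
#' @export
fuse_and_classify <- function(image_feature, graph_feature, params, config,
                              keep_cache = FALSE) {
  if (ncol(image_feature) != config$image_feature_dim ||
      ncol(graph_feature) != config$graph_feature_dim) {
    fh_stop("feature widths do not match config", "fh_invalid_input")
  }
  fused <- cbind(image_feature, graph_feature)
  l1 <- linear_forward(fused, params[["fuse.fc1.W"]], params[["fuse.fc1.b"]])
  r1 <- relu_forward(l1$out)
  l2 <- linear_forward(r1$out, params[["fuse.fc2.W"]], params[["fuse.fc2.b"]])
  list(logits = l2$out, fused = fused,
       cache = if (keep_cache) list(fc1 = l1$cache, r1 = r1$cache,
                                    fc2 = l2$cache) else NULL)
}

.fh_fusion_backward <- function(dlogits, cache, config) {
  g <- list()
  r <- linear_backward(dlogits, cache$fc2)
  g[["fuse.fc2.W"]] <- r$dW; g[["fuse.fc2.b"]] <- r$db
  dd <- relu_backward(r$dx, cache$r1)
  r <- linear_backward(dd, cache$fc1)
  g[["fuse.fc1.W"]] <- r$dW; g[["fuse.fc1.b"]] <- r$db
  list(grads = g, dfused = r$dx)
}

#' Full hybrid forward pass
#'
#' Runs both branches and the fusion head on paired inputs. The concatenated
#' pre-fusion feature (`fused`) is the representation the model-contrastive
#' loss operates on.
#'
#' @param images List of images (or `[H, W, 1, B]` array).
#' @param graphs List of `lesion_graph`s (or a batched graph), paired
#'   index-wise with `images`.
#' @param params,config,train,keep_cache As in [image_branch_forward()].
#' @return List with `image_feature`, `graph_feature`, `fused`, `logits`,
#'   `prob` (softmax malignancy probability), `caches`, `bn_updates`.
#' @export
hybrid_forward <- function(images, graphs, params, config, train = FALSE,
                           keep_cache = FALSE) {
  ib <- image_branch_forward(images, params, config, train, keep_cache)
  gb <- graph_branch_forward(graphs, params, config, train, keep_cache)
  fz <- fuse_and_classify(ib$feature, gb$feature, params, config, keep_cache)
  list(image_feature = ib$feature, graph_feature = gb$feature,
       fused = fz$fused, logits = fz$logits,
       prob = softmax_prob(fz$logits)[, 2],
       caches = list(img = ib$cache, gin = gb$cache, fuse = fz$cache),
       bn_updates = c(ib$bn_updates, gb$bn_updates))
}

#' Softmax probabilities from logits
#' @param logits B x K matrix of unnormalised scores.
#' @return B x K matrix of class probabilities.
#' @export
softmax_prob <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

## full backward: dlogits (B x 2) plus optional extra gradient on the fused
## feature (from the contrastive terms); returns flat grad list
.fh_hybrid_backward <- function(dlogits, dfused_extra, caches, params, config) {
  fb <- .fh_fusion_backward(dlogits, caches$fuse, config)
  dfused <- fb$dfused
  if (!is.null(dfused_extra)) dfused <- dfused + dfused_extra
  di <- dfused[, seq_len(config$image_feature_dim), drop = FALSE]
  dg <- dfused[, config$image_feature_dim + seq_len(config$graph_feature_dim),
               drop = FALSE]
  c(fb$grads,
    .fh_image_branch_backward(di, caches$img, params, config),
    .fh_graph_branch_backward(dg, caches$gin, params, config))
}

#' Save model parameters to a single-file checkpoint
#'
#' Format: an 8-byte little-endian header length, a JSON manifest of named
#' parameter blocks (name, dim, byte offset into the payload), then the
#' blocks as little-endian doubles.
#'
#' @param params Flat named parameter list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(params, path) {
  offs <- 0
  manifest <- lapply(names(params), function(nm) {
    x <- params[[nm]]
    d <- if (is.null(dim(x))) length(x) else dim(x)
    rec <- list(name = nm, dim = as.integer(d), offset = offs)
    offs <<- offs + length(x) * 8
    rec
  })
  hdr <- charToRaw(jsonlite::toJSON(manifest, auto_unbox = FALSE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(length(hdr)), con, size = 8, endian = "little")
  writeBin(hdr, con)
  for (x in params) writeBin(as.double(x), con, size = 8, endian = "little")
  invisible(path)
}

#' Load model parameters from a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint path.
#' @return Flat named parameter list.
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1, size = 8, endian = "little")
  manifest <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)),
                                 simplifyVector = FALSE)
  params <- list()
  for (rec in manifest) {
    d <- unlist(rec$dim)
    x <- readBin(con, "double", prod(d), size = 8, endian = "little")
    if (length(d) > 1) dim(x) <- d
    params[[unlist(rec$name)]] <- x
  }
  params
}
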
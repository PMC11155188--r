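#' Federated training configuration
#'
#' @param local_epochs Local epochs per communication round (k).
#' @param communication_rounds Number of broadcast / local-train / aggregate
#'   cycles.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum (0 disables).
#' @param hinge_margin Margin of the hinge-embedding term (> 0).
#' @param batch_size Mini-batch size.
#' @param finetune_epochs Epochs of per-center fine-tuning after federation.
#' @param use_prev_term,use_global_term Enable the two feature-contrastive
#'   terms of the composite loss (both TRUE by default; with both FALSE the
#'   loss is plain cross-entropy).
#' @param prev_target,global_target Hinge-embedding role of each feature
#'   pair: `"dissimilar"` pushes apart (loss `max(0, margin - d)`),
#'   `"similar"` pulls together (loss `d`). Defaults follow the
#'   model-contrastive reading: the previous-epoch local feature is the
#'   dissimilar pair, the global-model feature the similar pair.
#' @param feature_distance Distance for the contrastive terms:
#'   `"normalized"` (chord distance between L2-normalised feature rows,
#'   default; scale-invariant and bounded by 2) or `"euclidean"` (raw
#'   features, meaningful only when the compared models' activation scales
#'   are commensurate).
#' @param seed Integer seed; all shuffling, dropout and initialisation derive
#'   from it.
#' @return An object of class `fed_config`.
#' @export
fed_config <- function(local_epochs = 2, communication_rounds = 3,
                       learning_rate = 0.02, momentum = 0.9,
                       hinge_margin = 1, batch_size = 16,
                       finetune_epochs = 5, use_prev_term = TRUE,
                       use_global_term = TRUE,
                       prev_target = c("dissimilar", "similar"),
                       global_target = c("similar", "dissimilar"),
                       feature_distance = c("normalized", "euclidean"),
                       seed = 1) {
  if (local_epochs < 1 || communication_rounds < 1) {
    fh_stop("local_epochs and communication_rounds must be >= 1", "fh_invalid_config")
  }
  if (hinge_margin <= 0) fh_stop("hinge_margin must be > 0", "fh_invalid_config")
  structure(list(local_epochs = as.integer(local_epochs),
                 communication_rounds = as.integer(communication_rounds),
                 learning_rate = learning_rate, momentum = momentum,
                 hinge_margin = hinge_margin,
                 batch_size = as.integer(batch_size),
                 finetune_epochs = as.integer(finetune_epochs),
                 use_prev_term = isTRUE(use_prev_term),
                 use_global_term = isTRUE(use_global_term),
                 prev_target = match.arg(prev_target),
                 global_target = match.arg(global_target),
                 feature_distance = match.arg(feature_distance),
                 seed = as.integer(seed)),
            class = "fed_config")
}

#' Size-weighted parameter aggregation (federated averaging)
#'
#' Block-wise convex combination `w_glob <- sum_i (n_i / N) w_i` over
#' shape-compatible parameter lists.
#'
#' @param clients List of `list(params = <flat named list>, n = <count>)`.
#' @return The aggregated flat named parameter list.
#' @export
#' @examples
#' a <- list(w = 0); b <- list(w = 1)
#' aggregate_params(list(list(params = a, n = 1), list(params = b, n = 3)))$w
aggregate_params <- function(clients) {
  if (length(clients) < 1) fh_stop("need at least one client", "fh_aggregation_error")
  ref <- names(clients[[1]]$params)
  for (cl in clients) {
    if (!identical(names(cl$params), ref) ||
        !all(mapply(function(a, b) identical(dim(a), dim(b)) && length(a) == length(b),
                    cl$params, clients[[1]]$params))) {
      fh_stop("client parameter blocks are not shape-compatible", "fh_aggregation_error")
    }
  }
  n <- vapply(clients, `[[`, numeric(1), "n")
  wts <- n / sum(n)
  out <- clients[[1]]$params
  for (nm in ref) {
    acc <- clients[[1]]$params[[nm]] * wts[1]
    if (length(clients) > 1) {
      for (i in 2:length(clients)) acc <- acc + clients[[i]]$params[[nm]] * wts[i]
    }
    out[[nm]] <- acc
  }
  out
}

#' Total parameter count of a flat parameter list
#' @param params Flat named parameter list.
#' @return Integer count.
#' @export
param_total_size <- function(params) sum(vapply(params, length, integer(1)))

## batch-mean Euclidean distance between feature rows, with gradient w.r.t.
## the first argument. The default "normalized" variant measures the distance
## between L2-normalised rows (the chord distance): it is scale-invariant and
## bounded by 2, so a fixed hinge margin stays meaningful whatever the
## feature magnitudes of the two models being compared. "euclidean" is the
## plain distance on raw features.
.fh_pair_dist <- function(f_curr, f_other, distance = "normalized") {
  B <- nrow(f_curr)
  if (distance == "euclidean") {
    diff <- f_curr - f_other
    dn <- sqrt(rowSums(diff^2))
    grad <- diff / ifelse(dn > 1e-12, dn, Inf) / B
    return(list(d = mean(dn), grad = grad))
  }
  nc_ <- sqrt(rowSums(f_curr^2))
  no_ <- sqrt(rowSums(f_other^2))
  u <- f_curr / ifelse(nc_ > 1e-12, nc_, Inf)
  v <- f_other / ifelse(no_ > 1e-12, no_, Inf)
  diff <- u - v
  dn <- sqrt(rowSums(diff^2))
  w <- diff / ifelse(dn > 1e-12, dn, Inf)
  ## chain through the normalisation: project onto the unit sphere's tangent
  proj <- w - u * rowSums(w * u)
  grad <- proj / ifelse(nc_ > 1e-12, nc_, Inf) / B
  list(d = mean(dn), grad = grad)
}

#' Composite federated loss (cross-entropy + two hinge-embedding terms)
#'
#' `L = CE(logits, label) + HE(f_prev_local, f_curr) + HE(f_global, f_curr)`
#' where the hinge-embedding distance `d` is the Euclidean distance between
#' paired feature rows averaged over the batch. By default the rows are
#' L2-normalised first (`distance = "normalized"`, the chord distance,
#' bounded by 2, so the margin keeps its meaning regardless of the two
#' models' feature scales); `distance = "euclidean"` uses the raw features,
#' which is only advisable when the compared models' activation scales are
#' already commensurate. Under the default
#' model-contrastive convention the previous-epoch local pair is
#' "dissimilar" (contributes `max(0, margin - d)`, pushing the representation
#' away from its stale self) and the global pair is "similar" (contributes
#' `d`, pulling it toward the broadcast global model). A `NULL` feature
#' argument drops its term (e.g. the very first epoch has no previous
#' feature).
#'
#' @param logits B x 2 matrix of class scores.
#' @param labels Integer vector of 0/1 labels.
#' @param f_prev_local,f_curr_local,f_global B x d feature matrices
#'   (`f_prev_local` and `f_global` may be NULL).
#' @param margin Hinge margin (> 0).
#' @param prev_target,global_target `"dissimilar"` or `"similar"` (see
#'   [fed_config()]).
#' @param distance `"normalized"` (chord distance between L2-normalised
#'   rows, default) or `"euclidean"` (raw features).
#' @return List with `loss`, `parts` (ce, prev, global), `dlogits` and
#'   `dfused` (gradients w.r.t. logits and the current feature).
#' @export
composite_loss <- function(logits, labels, f_prev_local = NULL,
                           f_curr_local = NULL, f_global = NULL, margin = 1,
                           prev_target = "dissimilar",
                           global_target = "similar",
                           distance = c("normalized", "euclidean")) {
  distance <- match.arg(distance)
  B <- nrow(logits)
  if (length(labels) != B) fh_stop("logits/labels length mismatch", "fh_invalid_input")
  p <- softmax_prob(logits)
  y <- cbind(labels == 0, labels == 1)
  ce <- -mean(log(pmax(p[y], 1e-12)))
  dlogits <- (p - y) / B
  dfused <- NULL
  hinge <- function(f_other, target) {
    if (is.null(f_other)) return(list(term = 0, grad = NULL))
    if (!is.null(f_curr_local) && ncol(f_other) != ncol(f_curr_local)) {
      fh_stop("feature length mismatch", "fh_invalid_input")
    }
    pd <- .fh_pair_dist(f_curr_local, f_other, distance)
    if (target == "similar") {
      list(term = pd$d, grad = pd$grad)
    } else if (pd$d < margin) {
      list(term = margin - pd$d, grad = -pd$grad)
    } else {
      list(term = 0, grad = NULL)
    }
  }
  hp <- hinge(f_prev_local, prev_target)
  hg <- hinge(f_global, global_target)
  for (gg in list(hp$grad, hg$grad)) {
    if (!is.null(gg)) dfused <- if (is.null(dfused)) gg else dfused + gg
  }
  list(loss = ce + hp$term + hg$term,
       parts = c(ce = ce, prev = hp$term, global = hg$term),
       dlogits = dlogits, dfused = dfused)
}

## one SGD step with momentum; returns list(params, velocity)
.fh_sgd_step <- function(params, grads, velocity, lr, momentum) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    ## gradients can pick up dimnames from the data (e.g. node feature
    ## columns); keep parameter arrays attribute-clean
    if (is.null(dim(g))) names(g) <- NULL else dimnames(g) <- NULL
    v <- velocity[[nm]]
    v <- if (is.null(v)) -lr * g else momentum * v - lr * g
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
  list(params = params, velocity = velocity)
}

## evaluate malignancy probabilities with a parameter set (eval mode)
.fh_predict_probs <- function(params, net_config, images, graphs,
                              chunk = 64L) {
  n <- length(images)
  probs <- numeric(n)
  for (st in seq(1, n, by = chunk)) {
    ii <- st:min(st + chunk - 1, n)
    fw <- hybrid_forward(images[ii], graphs[ii], params, net_config,
                         train = FALSE)
    probs[ii] <- fw$prob
  }
  probs
}

## fused features of a whole dataset in eval mode (batch-independent because
## evaluation-mode batch norm uses running statistics and dropout is off)
.fh_fused_features <- function(params, net_config, data, chunk = 64L) {
  n <- length(data$labels)
  fdim <- net_config$image_feature_dim + net_config$graph_feature_dim
  out <- matrix(NA_real_, n, fdim, dimnames = list(data$ids, NULL))
  for (st in seq(1, n, by = chunk)) {
    ii <- st:min(st + chunk - 1, n)
    fw <- hybrid_forward(data$images[ii], data$graphs[ii], params, net_config,
                         train = FALSE)
    out[ii, ] <- fw$fused
  }
  out
}

#' Train a client's local model for k epochs
#'
#' Initialises the local parameters from the broadcast global model and runs
#' `k` epochs of mini-batch SGD on the composite loss. The per-sample fused
#' features computed during each epoch become the "previous" features of the
#' next epoch (the very first epoch of training has none, so its term is
#' dropped); the global feature is computed by a frozen copy of the broadcast
#' parameters.
#'
#' @param client List with `center_id`, `data` (a list with `images`,
#'   `graphs`, `labels`, `ids`), and optionally `prev_features` from an
#'   earlier round.
#' @param global_params Broadcast global parameter list.
#' @param k Number of local epochs.
#' @param config A [fed_config()].
#' @param net_config A [hybrid_config()].
#' @param round Communication-round index (seeds the epoch shuffles).
#' @param log_sink Optional JSON-lines log sink.
#' @return The updated client: `params`, refreshed `prev_features`, per-epoch
#'   `loss_history`, cumulative `steps`, and `touched_ids` (audit trail).
#' @export
local_train <- function(client, global_params, k, config, net_config,
                        round = 1, log_sink = NULL) {
  data <- client$data
  n <- length(data$labels)
  if (n == 0) fh_stop("client has no data", "fh_invalid_state")
  params <- global_params
  velocity <- list()
  prev <- client$prev_features
  steps <- 0L
  loss_hist <- numeric(0)
  fdim <- net_config$image_feature_dim + net_config$graph_feature_dim
  ## the broadcast model is frozen for the whole call, so its features are
  ## computed once up front (eval-mode forwards are batch-independent)
  glob_feats <- if (config$use_global_term) {
    .fh_fused_features(global_params, net_config, data)
  } else NULL
  for (epoch in seq_len(k)) {
    set.seed(derive_seed(config$seed, "local", client$center_id, round, epoch))
    perm <- sample.int(n)
    new_feats <- matrix(NA_real_, n, fdim, dimnames = list(data$ids, NULL))
    ep_loss <- 0
    for (st in seq(1, n, by = config$batch_size)) {
      ii <- perm[st:min(st + config$batch_size - 1, n)]
      fw <- hybrid_forward(data$images[ii], data$graphs[ii], params,
                           net_config, train = TRUE, keep_cache = TRUE)
      f_prev <- if (config$use_prev_term && !is.null(prev) &&
                    all(data$ids[ii] %in% rownames(prev))) {
        prev[data$ids[ii], , drop = FALSE]
      } else NULL
      f_glob <- if (!is.null(glob_feats)) glob_feats[ii, , drop = FALSE] else NULL
      ls <- composite_loss(fw$logits, data$labels[ii], f_prev, fw$fused,
                           f_glob, margin = config$hinge_margin,
                           prev_target = config$prev_target,
                           global_target = config$global_target,
                           distance = config$feature_distance %||% "normalized")
      grads <- .fh_hybrid_backward(ls$dlogits, ls$dfused, fw$caches, params,
                                   net_config)
      upd <- .fh_sgd_step(params, grads, velocity, config$learning_rate,
                          config$momentum)
      params <- upd$params
      velocity <- upd$velocity
      for (nm in names(fw$bn_updates)) {
        params[[paste0(nm, ".rm")]] <- fw$bn_updates[[nm]]$rm
        params[[paste0(nm, ".rv")]] <- fw$bn_updates[[nm]]$rv
      }
      new_feats[ii, ] <- fw$fused
      steps <- steps + 1L
      ep_loss <- ep_loss + ls$loss * length(ii)
      fh_log(log_sink, list(event = "step", center = client$center_id,
                            round = round, epoch = epoch,
                            loss = unname(ls$loss),
                            ce = unname(ls$parts["ce"]),
                            prev = unname(ls$parts["prev"]),
                            global = unname(ls$parts["global"])))
    }
    prev <- new_feats
    loss_hist <- c(loss_hist, ep_loss / n)
  }
  client$params <- params
  client$prev_features <- prev
  client$loss_history <- c(client$loss_history, loss_hist)
  client$steps <- (client$steps %||% 0L) + steps
  client$touched_ids <- unique(c(client$touched_ids, data$ids))
  client
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run simulated federated training across centers
#'
#' Repeats (broadcast -> local training for k epochs per client ->
#' size-weighted aggregation) for the configured number of communication
#' rounds, starting from one seeded global initialisation. Per-round
#' validation metrics are recorded per center when validation data is
#' supplied. The only artifact that crosses a client boundary is the
#' parameter list.
#'
#' @param centers Named list of center datasets; each must have `$train`
#'   (images/graphs/labels/ids) and may have `$val`.
#' @param net_config A [hybrid_config()].
#' @param config A [fed_config()].
#' @param init_params Optional initial global parameters (defaults to a
#'   seeded [init_hybrid_params()]).
#' @param log_sink Optional JSON-lines log sink.
#' @return List with `global_params`, `clients` (final client states),
#'   `history` (per-round records), and `audit` (per-center ids touched).
#' @export
run_federated <- function(centers, net_config = hybrid_config(),
                          config = fed_config(), init_params = NULL,
                          log_sink = NULL) {
  if (length(centers) < 1) fh_stop("need at least one center", "fh_invalid_state")
  global <- init_params %||% init_hybrid_params(net_config, config$seed)
  clients <- lapply(names(centers), function(id) {
    list(center_id = id, data = centers[[id]]$train, prev_features = NULL)
  })
  names(clients) <- names(centers)
  history <- list()
  for (r in seq_len(config$communication_rounds)) {
    for (id in names(clients)) {
      clients[[id]] <- local_train(clients[[id]], global,
                                   config$local_epochs, config, net_config,
                                   round = r, log_sink = log_sink)
    }
    global <- aggregate_params(lapply(clients, function(cl) {
      list(params = cl$params, n = length(cl$data$labels))
    }))
    val <- lapply(names(clients), function(id) {
      v <- centers[[id]]$val
      if (is.null(v) || length(v$labels) == 0) return(NULL)
      probs <- .fh_predict_probs(global, net_config, v$images, v$graphs)
      cm <- confusion(probs, v$labels)
      m <- metrics_from_confusion(cm["TP"], cm["FP"], cm["TN"], cm["FN"])
      list(center = id, balanced_accuracy = m$balanced_accuracy)
    })
    names(val) <- names(clients)
    history[[r]] <- list(round = r, aggregated = TRUE,
                         local_loss = lapply(clients, function(cl) {
                           utils::tail(cl$loss_history, config$local_epochs)
                         }),
                         val = val)
    fh_log(log_sink, list(event = "aggregate", round = r))
  }
  list(global_params = global, clients = clients, history = history,
       audit = lapply(clients, `[[`, "touched_ids"))
}

## Re-estimate batch-normalisation running statistics over a dataset.
##
## After a handful of aggressive fine-tuning steps the weights have adapted
## to the local data but the exponentially averaged running statistics still
## largely reflect the pre-fine-tuning (federated) activations, so
## evaluation-mode predictions can be badly miscalibrated even on the very
## data the model was just fitted to. This sets each BN layer's running mean
## and variance to the batch-size-weighted average of the batch statistics
## observed over one full pass of `data`. Batch statistics are recovered
## exactly from the momentum update reported by the forward pass.
.fh_recalibrate_bn <- function(params, net_config, data, batch_size = 64L) {
  n <- length(data$labels)
  if (n == 0) return(params)
  acc <- list()
  w_tot <- 0
  for (st in seq(1, n, by = batch_size)) {
    ii <- st:min(st + batch_size - 1L, n)
    w <- length(ii)
    fw <- hybrid_forward(data$images[ii], data$graphs[ii], params, net_config,
                         train = TRUE)
    for (nm in names(fw$bn_updates)) {
      ## invert rm_new = 0.9 rm_old + 0.1 mu to recover the batch moments
      mu <- (fw$bn_updates[[nm]]$rm - 0.9 * params[[paste0(nm, ".rm")]]) / 0.1
      va <- (fw$bn_updates[[nm]]$rv - 0.9 * params[[paste0(nm, ".rv")]]) / 0.1
      if (is.null(acc[[nm]])) acc[[nm]] <- list(rm = w * mu, rv = w * va)
      else acc[[nm]] <- list(rm = acc[[nm]]$rm + w * mu,
                             rv = acc[[nm]]$rv + w * va)
    }
    w_tot <- w_tot + w
  }
  for (nm in names(acc)) {
    params[[paste0(nm, ".rm")]] <- acc[[nm]]$rm / w_tot
    params[[paste0(nm, ".rv")]] <- pmax(acc[[nm]]$rv / w_tot, 0)
  }
  params
}

#' Fine-tune a pretrained model on one center's data
#'
#' Continues optimisation on a single center's training split with plain
#' cross-entropy (after federation ends there is no global model to contrast
#' against; the contrastive terms can be re-enabled via `use_contrastive`).
#' Afterwards the batch-normalisation running statistics are re-estimated
#' over the center's training split (see `recalibrate`): a few aggressive
#' fine-tuning steps adapt the weights faster than the exponentially averaged
#' statistics can follow, which otherwise leaves evaluation-mode predictions
#' miscalibrated even on the fine-tuning data itself.
#'
#' @param global_params Pretrained (federated) parameter list.
#' @param center_data Center dataset (uses `$train`).
#' @param epochs Number of fine-tuning epochs (0 returns the parameters
#'   unchanged).
#' @param config A [fed_config()].
#' @param net_config A [hybrid_config()].
#' @param center_id Center label (seeds and audit).
#' @param use_contrastive Keep the contrastive terms during fine-tuning
#'   (default FALSE).
#' @param recalibrate Re-estimate batch-norm running statistics on the
#'   center's training split after the gradient steps (default TRUE).
#' @param log_sink Optional log sink.
#' @return List with `params`, `loss_history` and `touched_ids`.
#' @export
fine_tune <- function(global_params, center_data, epochs, config,
                      net_config, center_id = "finetune",
                      use_contrastive = FALSE, recalibrate = TRUE,
                      log_sink = NULL) {
  if (epochs == 0) {
    return(list(params = global_params, loss_history = numeric(0),
                touched_ids = character(0)))
  }
  cfg <- config
  if (!use_contrastive) {
    cfg$use_prev_term <- FALSE
    cfg$use_global_term <- FALSE
  }
  client <- list(center_id = paste0("ft-", center_id),
                 data = center_data$train, prev_features = NULL)
  client <- local_train(client, global_params, epochs, cfg, net_config,
                        round = 1, log_sink = log_sink)
  params <- client$params
  if (recalibrate) {
    set.seed(derive_seed(cfg$seed, "recalibrate", center_id))
    params <- .fh_recalibrate_bn(params, net_config, center_data$train,
                                 batch_size = cfg$batch_size)
  }
  list(params = params, loss_history = client$loss_history,
       touched_ids = client$touched_ids)
}

#' Centralized training on a single dataset
#'
#' The non-federated reference: the same optimisation loop as one federated
#' client, with the "global" snapshot refreshed from the model itself every
#' `local_epochs` epochs. With a single center and shared seed this coincides
#' exactly (bitwise) with [run_federated()] on that center.
#'
#' @param center_data Center dataset (uses `$train`).
#' @param net_config A [hybrid_config()].
#' @param config A [fed_config()].
#' @param center_id Center label used in seed derivation (must match the
#'   federated center name for the equivalence to hold).
#' @param init_params Optional initial parameters.
#' @return List with `params` and the client state.
#' @export
centralized_train <- function(center_data, net_config = hybrid_config(),
                              config = fed_config(), center_id = "center",
                              init_params = NULL) {
  params <- init_params %||% init_hybrid_params(net_config, config$seed)
  client <- list(center_id = center_id, data = center_data$train,
                 prev_features = NULL)
  for (r in seq_len(config$communication_rounds)) {
    snapshot <- params
    client <- local_train(client, snapshot, config$local_epochs, config,
                          net_config, round = r)
    params <- client$params
  }
  list(params = params, client = client)
}
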
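#' Prepare one center's dataset for training
#'
#' Resizes every image to the working side, performs the stratified
#' train/validation/test split, builds one lesion graph per source image
#' (from the resized, un-augmented image), and expands the training split by
#' randomized augmentation. Each augmented copy is paired with the graph of
#' its source image; validation and test samples stay un-augmented.
#'
#' @param samples List of samples (image/label/center_id/sample_id).
#' @param side Working image side (default 32).
#' @param graph_cfg A [graph_config()].
#' @param split A [split_spec()].
#' @param augment An [augment_params()].
#' @param seed Seed for the augmentation expansion.
#' @return List with `train`, `val`, `test` (each images/graphs/labels/ids),
#'   `split` (index sets), and `n_source`.
#' @export
prepare_center <- function(samples, side = 32, graph_cfg = graph_config(),
                           split = split_spec(), augment = augment_params(),
                           seed = 1) {
  images <- lapply(samples, function(s) resize_image(s$image, side))
  labels <- vapply(samples, `[[`, integer(1), "label")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  center <- samples[[1]]$center_id
  graphs <- lapply(seq_along(samples), function(i) {
    image_to_graph(images[[i]], graph_cfg, label = labels[i],
                   sample_id = ids[i])
  })
  idx <- stratified_split(labels, split)
  subset_of <- function(ii) {
    list(images = images[ii], graphs = graphs[ii], labels = labels[ii],
         ids = ids[ii])
  }
  train_src <- lapply(idx$train, function(i) {
    list(image = images[[i]], label = labels[i], center_id = center,
         sample_id = ids[i])
  })
  aug <- augment_tenfold(train_src, augment, seed = seed)
  graph_of <- stats::setNames(graphs[idx$train], ids[idx$train])
  train <- list(images = lapply(aug, `[[`, "image"),
                graphs = graph_of[vapply(aug, `[[`, character(1), "src_id")],
                labels = vapply(aug, `[[`, integer(1), "label"),
                ids = vapply(aug, `[[`, character(1), "sample_id"))
  list(train = train, val = subset_of(idx$val), test = subset_of(idx$test),
       split = idx, n_source = length(samples), center_id = center)
}

#' Fit the federated hybrid classifier
#'
#' The package's main fitting function. Takes raw per-center samples,
#' prepares them (resize, stratified split, graph construction, tenfold
#' augmentation), pretrains one global model by federated averaging with the
#' model-contrastive composite loss, fine-tunes a copy per center, and
#' evaluates every center's fine-tuned model on that center's held-out test
#' split.
#'
#' @param centers Named list of sample lists (e.g. from
#'   [generate_three_centers()]), or already-prepared datasets from
#'   [prepare_center()] (detected by the presence of `$train`).
#' @param net_config A [hybrid_config()].
#' @param config A [fed_config()].
#' @param graph_cfg A [graph_config()].
#' @param split A [split_spec()].
#' @param augment An [augment_params()].
#' @param finetune Fine-tune per center after federation (default TRUE).
#' @param log_sink Optional JSON-lines log sink.
#' @return An object of class `fedhybrid` with elements `global_params`,
#'   `finetuned` (per-center parameter lists), `history`, `eval` (per-center
#'   [evaluate_predictions()] reports plus a pooled report), `data_sizes`,
#'   and the configurations. Methods: [print.fedhybrid()],
#'   [summary.fedhybrid()], [predict.fedhybrid()], [plot.fedhybrid()].
#' @export
fedhybrid <- function(centers, net_config = hybrid_config(),
                      config = fed_config(), graph_cfg = graph_config(),
                      split = split_spec(), augment = augment_params(),
                      finetune = TRUE, log_sink = NULL) {
  prepared <- lapply(names(centers), function(id) {
    cd <- centers[[id]]
    if (!is.null(cd$train)) cd
    else prepare_center(cd, side = net_config$image_size, graph_cfg = graph_cfg,
                        split = split, augment = augment,
                        seed = derive_seed(config$seed, "prepare", id))
  })
  names(prepared) <- names(centers)
  fed <- run_federated(prepared, net_config, config, log_sink = log_sink)
  finetuned <- NULL
  if (finetune) {
    finetuned <- lapply(names(prepared), function(id) {
      fine_tune(fed$global_params, prepared[[id]], config$finetune_epochs,
                config, net_config, center_id = id, log_sink = log_sink)$params
    })
    names(finetuned) <- names(prepared)
  }
  eval_params <- finetuned %||% stats::setNames(
    rep(list(fed$global_params), length(prepared)), names(prepared))
  all_probs <- numeric(0); all_labels <- integer(0)
  evals <- lapply(names(prepared), function(id) {
    te <- prepared[[id]]$test
    if (length(te$labels) == 0) return(NULL)
    probs <- .fh_predict_probs(eval_params[[id]], net_config, te$images,
                               te$graphs)
    all_probs <<- c(all_probs, probs)
    all_labels <<- c(all_labels, te$labels)
    evaluate_predictions(probs, te$labels)
  })
  names(evals) <- names(prepared)
  pooled <- if (length(all_labels)) evaluate_predictions(all_probs, all_labels) else NULL
  structure(list(global_params = fed$global_params, finetuned = finetuned,
                 history = fed$history, audit = fed$audit,
                 eval = list(per_center = evals, pooled = pooled),
                 data_sizes = lapply(prepared, function(p) {
                   c(train = length(p$train$labels), val = length(p$val$labels),
                     test = length(p$test$labels))
                 }),
                 net_config = net_config, fed_config = config,
                 graph_cfg = graph_cfg),
            class = "fedhybrid")
}

#' @export
print.fedhybrid <- function(x, ...) {
  cat("Federated hybrid spatial-geometric classifier\n")
  cat(sprintf("  image branch: pre-activation ResNet, depth %d (%d blocks/stage), feature %d\n",
              x$net_config$image_depth, x$net_config$blocks_per_stage,
              x$net_config$image_feature_dim))
  cat(sprintf("  graph branch: %d edge-aware GIN blocks, width %d, %s pooling\n",
              x$net_config$gin_blocks, x$net_config$graph_hidden,
              x$net_config$readout))
  cat(sprintf("  federated: %d rounds x %d local epochs over %d centers%s\n",
              x$fed_config$communication_rounds, x$fed_config$local_epochs,
              length(x$data_sizes),
              if (is.null(x$finetuned)) "" else ", fine-tuned per center"))
  if (!is.null(x$eval$pooled)) {
    cat(sprintf("  pooled test balanced accuracy: %.3f (n = %d)\n",
                x$eval$pooled$balanced_accuracy, x$eval$pooled$n))
  }
  invisible(x)
}

#' @export
summary.fedhybrid <- function(object, ...) {
  print(object)
  cat("\nPer-center data sizes (train is post-augmentation):\n")
  print(do.call(rbind, object$data_sizes))
  cat("\nPer-center test metrics:\n")
  for (id in names(object$eval$per_center)) {
    r <- object$eval$per_center[[id]]
    if (is.null(r)) next
    cat(sprintf("  %s: bal.acc %.3f  sens %.3f  spec %.3f  F1 %.3f  AUC-ROC %.3f  AUC-PR %.3f\n",
                id, r$balanced_accuracy, r$sensitivity, r$specificity, r$f1,
                r$auc_roc, r$auc_pr))
  }
  invisible(object)
}

#' Predict malignancy probabilities for new samples
#'
#' @param object A fitted [fedhybrid()] model.
#' @param samples List of samples (each with `$image`; labels optional), or a
#'   prepared subset with `$images` and `$graphs`.
#' @param center Which center's fine-tuned model to use; `NULL` (default)
#'   uses the global federated model.
#' @param type `"prob"` for malignancy probabilities, `"class"` for 0/1
#'   calls at threshold 0.5.
#' @param ... Unused.
#' @return Numeric (prob) or integer (class) vector.
#' @export
predict.fedhybrid <- function(object, samples, center = NULL,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  params <- if (is.null(center)) object$global_params
            else object$finetuned[[center]] %||% object$global_params
  if (!is.null(samples$images)) {
    images <- samples$images; graphs <- samples$graphs
  } else {
    images <- lapply(samples, function(s) resize_image(s$image, object$net_config$image_size))
    graphs <- lapply(images, image_to_graph, config = object$graph_cfg)
  }
  probs <- .fh_predict_probs(params, object$net_config, images, graphs)
  if (type == "prob") probs else as.integer(probs >= 0.5)
}

#' Plot federated training history
#'
#' Per-round validation balanced accuracy of the global model on each
#' center's validation split.
#'
#' @param x A fitted [fedhybrid()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fedhybrid <- function(x, ...) {
  rounds <- seq_along(x$history)
  ids <- names(x$data_sizes)
  vals <- sapply(ids, function(id) {
    vapply(x$history, function(h) {
      v <- h$val[[id]]
      if (is.null(v)) NA_real_ else v$balanced_accuracy
    }, numeric(1))
  })
  vals <- matrix(vals, nrow = length(rounds))
  graphics::matplot(rounds, vals, type = "b", pch = seq_along(ids),
                    xlab = "communication round",
                    ylab = "validation balanced accuracy", ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = ids, pch = seq_along(ids),
                   col = seq_along(ids), bty = "n")
  invisible(x)
}
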
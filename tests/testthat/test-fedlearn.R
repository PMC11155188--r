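test_that("size-weighted aggregation matches a brute-force weighted mean", {
  set.seed(1)
  clients <- lapply(1:5, function(i) {
    list(params = random_param_list(10, seed = i), n = sample(1:500, 1))
  })
  agg <- aggregate_params(clients)
  n <- vapply(clients, `[[`, numeric(1), "n")
  for (nm in names(agg)) {
    brute <- Reduce(`+`, lapply(seq_along(clients), function(i) {
      clients[[i]]$params[[nm]] * n[i]
    })) / sum(n)
    expect_equal(agg[[nm]], brute, tolerance = 1e-12)
  }
})

test_that("aggregating a single client returns its parameters bit for bit", {
  p <- random_param_list(6, seed = 3)
  agg <- aggregate_params(list(list(params = p, n = 17)))
  expect_identical(agg, p)
})

test_that("aggregation rejects shape-incompatible clients", {
  a <- list(w = matrix(0, 2, 2))
  b <- list(w = matrix(0, 2, 3))
  expect_error(aggregate_params(list(list(params = a, n = 1),
                                     list(params = b, n = 1))),
               class = "fh_aggregation_error")
  expect_error(aggregate_params(list()), class = "fh_aggregation_error")
})

test_that("the composite loss matches a hand computation", {
  ## one sample, cross entropy fixed at 0.5 by construction
  l2 <- -log(exp(0.5) - 1)
  logits <- matrix(c(0, l2), 1, 2)
  ## unit feature rows at chord distances 0.3 (previous) and 0.2 (global)
  chord_vec <- function(ch) {
    ct <- 1 - ch^2 / 2
    matrix(c(ct, sqrt(1 - ct^2)), 1, 2)
  }
  f_curr <- matrix(c(1, 0), 1, 2)
  ls <- composite_loss(logits, labels = 1L, f_prev_local = chord_vec(0.3),
                       f_curr_local = f_curr, f_global = chord_vec(0.2),
                       margin = 1)
  ## CE 0.5 + dissimilar hinge (1 - 0.3) + similar pull 0.2
  expect_equal(unname(ls$parts["ce"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(ls$parts["prev"]), 0.7, tolerance = 1e-10)
  expect_equal(unname(ls$parts["global"]), 0.2, tolerance = 1e-10)
  expect_equal(ls$loss, 1.4, tolerance = 1e-10)
})

test_that("with both feature terms absent the loss is plain cross entropy", {
  set.seed(4)
  logits <- matrix(rnorm(10), 5, 2)
  labels <- c(0L, 1L, 1L, 0L, 1L)
  ls <- composite_loss(logits, labels, NULL, NULL, NULL)
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  ce <- -mean(log(p[cbind(1:5, labels + 1)]))
  expect_equal(ls$loss, ce, tolerance = 1e-12)
  expect_identical(unname(ls$parts[c("prev", "global")]), c(0, 0))
  expect_null(ls$dfused)
})

test_that("a dissimilar pair beyond the margin contributes nothing", {
  logits <- matrix(c(0, 0), 1, 2)
  f_curr <- matrix(c(1, 0), 1, 2)
  f_far <- matrix(c(-1, 0), 1, 2)  # chord distance 2 > margin
  ls <- composite_loss(logits, 1L, f_prev_local = f_far,
                       f_curr_local = f_curr, f_global = NULL, margin = 1)
  expect_equal(unname(ls$parts["prev"]), 0)
})

test_that("the plain euclidean distance option matches a direct computation", {
  set.seed(15)
  f <- matrix(rnorm(20), 4, 5)
  g <- matrix(rnorm(20), 4, 5)
  pd <- fedhybrid:::.fh_pair_dist(f, g, distance = "euclidean")
  expect_equal(pd$d, mean(sqrt(rowSums((f - g)^2))), tolerance = 1e-12)
  ## hand case under the raw-distance convention
  l2 <- -log(exp(0.5) - 1)
  logits <- matrix(c(0, l2), 1, 2)
  ls <- composite_loss(logits, 1L,
                       f_prev_local = matrix(c(0.3, 0), 1, 2),
                       f_curr_local = matrix(c(0, 0), 1, 2),
                       f_global = matrix(c(0, 0.2), 1, 2),
                       margin = 1, distance = "euclidean")
  expect_equal(ls$loss, 1.4, tolerance = 1e-10)
})

test_that("the feature distance is invariant to feature scale", {
  set.seed(5)
  f <- matrix(rnorm(20), 4, 5)
  g <- matrix(rnorm(20), 4, 5)
  d1 <- fedhybrid:::.fh_pair_dist(f, g)$d
  d2 <- fedhybrid:::.fh_pair_dist(f * 1e6, g * 1e-3)$d
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_lte(d1, 2)
})

test_that("a zero learning rate leaves the weights untouched", {
  prep <- small_prepared()
  nc <- small_net()
  cfg <- fed_config(learning_rate = 0, momentum = 0, local_epochs = 1,
                    batch_size = 8, seed = 6)
  init <- init_hybrid_params(nc, 1)
  client <- list(center_id = "t", data = prep$train)
  out <- local_train(client, init, 1, cfg, nc)
  weight_names <- names(init)[!grepl("\\.(rm|rv)$", names(init))]
  for (nm in weight_names) expect_identical(out$params[[nm]], init[[nm]])
  ## batch-norm running statistics do update during forward passes
  expect_false(identical(out$params[["img.bnf.rm"]], init[["img.bnf.rm"]]))
})

test_that("single-client federated training equals centralized training bitwise", {
  prep <- small_prepared(n_benign = 6, n_malignant = 6, seed = 21)
  nc <- small_net()
  cfg <- fed_config(local_epochs = 1, communication_rounds = 2,
                    batch_size = 8, seed = 7)
  fed <- run_federated(list(only = prep), nc, cfg)
  cen <- centralized_train(prep, nc, cfg, center_id = "only")
  expect_identical(fed$global_params, cen$params)
})

test_that("local training touches exactly the training identifiers", {
  prep <- small_prepared()
  nc <- small_net()
  cfg <- fed_config(local_epochs = 1, communication_rounds = 1,
                    batch_size = 8, seed = 8)
  fed <- run_federated(list(c1 = prep), nc, cfg)
  expect_setequal(fed$audit$c1, prep$train$ids)
  expect_length(intersect(fed$audit$c1, prep$val$ids), 0)
  expect_length(intersect(fed$audit$c1, prep$test$ids), 0)
})

test_that("federated runs are reproducible under one seed", {
  prep <- small_prepared(n_benign = 5, n_malignant = 5, seed = 31)
  nc <- small_net()
  cfg <- fed_config(local_epochs = 1, communication_rounds = 1,
                    batch_size = 8, seed = 9)
  a <- run_federated(list(c1 = prep), nc, cfg)
  b <- run_federated(list(c1 = prep), nc, cfg)
  expect_identical(a$global_params, b$global_params)
})

test_that("fine-tuning with zero epochs is the identity", {
  nc <- small_net()
  p <- init_hybrid_params(nc, 2)
  prep <- small_prepared(n_benign = 4, n_malignant = 4, seed = 41)
  ft <- fine_tune(p, prep, 0, fed_config(seed = 10), nc)
  expect_identical(ft$params, p)
})
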
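test_that("classifier construction is seeded and sized as documented", {
  a <- build_classifier("linear_baseline", seed = 3L)
  b <- build_classifier("linear_baseline", seed = 3L)
  c <- build_classifier("linear_baseline", seed = 4L)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
  # 3 * (5600 + 1) parameters, no hidden layer
  expect_equal(n_parameters(a), 3L * (5600L + 1L))
  d1 <- build_classifier("dual_cnn", seed = 3L)
  d2 <- build_classifier("dual_cnn", seed = 3L)
  expect_identical(d1$params, d2$params)
  expect_error(build_classifier("svm"), "arg")
})

test_that("predicted probabilities live on the simplex with argmax labels", {
  ds <- toy_dataset(6L)
  for (spec in c("linear_baseline", "dual_cnn")) {
    st <- build_classifier(spec, seed = 5L)
    pred <- predict_proba(st, ds)
    expect_equal(dim(pred$probabilities), c(18L, 3L))
    expect_true(all(pred$probabilities >= 0))
    expect_equal(rowSums(pred$probabilities), rep(1, 18L),
                 tolerance = 1e-6)
    expect_equal(as.integer(pred$labels),
                 max.col(pred$probabilities, ties.method = "first"))
    # permuting the input order permutes the outputs identically
    perm <- c(5:18, 1:4)
    pred_p <- predict_proba(st, ds$signatures[, , perm])
    expect_equal(pred_p$probabilities, pred$probabilities[perm, ])
    expect_error(predict_proba(st, array(0, c(10, 10, 2))), "56 x 100")
  }
})

test_that("training warm-starts, is reproducible, and nails separable toys", {
  ds <- toy_dataset(15L)
  st0 <- build_classifier("linear_baseline", seed = 6L)
  # zero epochs must leave the parameters untouched
  expect_identical(train(st0, ds, train_folds = 1:4, epochs = 0L), st0)
  st1 <- train(st0, ds, train_folds = 1:4)
  st1b <- train(st0, ds, train_folds = 1:4)
  expect_identical(st1$params, st1b$params)
  # warm start: a second call continues from st1, changing the parameters
  st2 <- train(st1, ds, train_folds = 1:4)
  expect_false(identical(st1$params, st2$params))
  expect_equal(nrow(st2$history), 2L * st2$hyper$epochs)
  # separable toy: perfect training accuracy and held-out macro F1
  idx <- fold_indices(ds, 1:4)
  pred <- predict_proba(st1, ds$signatures[, , idx])
  expect_equal(mean(pred$labels == ds$labels[idx]), 1)
  expect_equal(evaluate_fold(st1, ds, 5L), 1)
  # training data missing a class is rejected
  sub <- dataset_subset(ds, which(ds$labels != "sural"))
  expect_error(train(build_classifier("linear_baseline"), sub,
                     indices = seq_along(sub$labels), labels = sub$labels),
               "absent")
})

test_that("the clean baseline dataset is almost perfectly separable", {
  cfg <- micro_config()
  ds <- cached("ds/clean", simulate_timepoint_dataset(cfg, "Base", 60,
                                                      fill = 0, seed = 1L))
  # more passes than the large-sample default: the micro training pool is
  # tiny, so one epoch is only a single parameter update
  st <- build_classifier("linear_baseline", seed = 8L,
                         hyper = list(epochs = 30L))
  st <- train(st, ds, train_folds = 1:4)
  expect_gte(evaluate_fold(st, ds, 5L), 0.99)
})

test_that("the dual-branch CNN learns and is interchangeable downstream", {
  ds <- toy_dataset(8L)
  st <- build_classifier("dual_cnn", seed = 9L,
                         hyper = list(epochs = 6L, lr = 0.01))
  st <- train(st, ds, train_folds = 1:4)
  # loss decreases over training
  expect_lt(st$history$loss[nrow(st$history)], st$history$loss[1])
  expect_equal(evaluate_fold(st, ds, 5L), 1)
  expect_identical(train(st, ds, train_folds = 1:4, epochs = 0L), st)
})

test_that("CNN backpropagation matches finite-difference gradients", {
  set.seed(11)
  arr <- array(rnorm(56 * 100 * 2, sd = 0.3), dim = c(56, 100, 2))
  y <- c(1L, 3L)
  st <- build_classifier("dual_cnn", seed = 12L,
                         hyper = list(filters = c(2L, 3L)))
  loss_of <- function(params) {
    attr(params, "branch_dims") <- attr(st$params, "branch_dims")
    st2 <- st
    st2$params <- params
    sc <- cuffdrift:::dual_cnn_scores(st2, arr)
    p <- cuffdrift:::softmax_rows(sc)
    -mean(log(p[cbind(1:2, y)]))
  }
  # analytic gradient via one full-batch step of plain accumulation
  grads <- lapply(st$params, function(p) p * 0)
  yk <- diag(3)
  for (s in 1:2) {
    fw <- cuffdrift:::dual_cnn_forward_one(st, arr[, , s])
    p <- exp(fw$score - max(fw$score)); p <- p / sum(p)
    dscore <- (p - yk[y[s], ]) / 2
    grads$W <- grads$W + outer(fw$f, dscore)
    grads$b <- grads$b + dscore
    df <- drop(st$params$W %*% dscore)
    nf <- fw$bd$flat
    grads <- cuffdrift:::branch_backward(df[seq_len(nf)], fw$sp, "sp",
                                         st$params, fw$k, fw$bd, grads)
    grads <- cuffdrift:::branch_backward(df[nf + seq_len(nf)], fw$tm, "tm",
                                         st$params, fw$k, fw$bd, grads)
  }
  eps <- 1e-5
  for (nm in c("sp.K1", "sp.b2", "tm.K2", "W", "b")) {
    pick <- sample(length(st$params[[nm]]), min(4, length(st$params[[nm]])))
    for (i in pick) {
      pp <- st$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      up <- loss_of(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      dn <- loss_of(pp)
      # tolerance accommodates finite-difference error at ReLU kinks
      expect_equal(grads[[nm]][i], (up - dn) / (2 * eps), tolerance = 0.02)
    }
  }
})

test_that("macro F1 matches a brute-force confusion-matrix oracle", {
  classes <- c("tibial", "peroneal", "sural")
  oracle <- function(pred, true) {
    pred <- factor(pred, classes); true <- factor(true, classes)
    cm <- table(true, pred)
    mean(vapply(classes, function(cl) {
      p <- if (sum(cm[, cl]) == 0) 0 else cm[cl, cl] / sum(cm[, cl])
      r <- if (sum(cm[cl, ]) == 0) 0 else cm[cl, cl] / sum(cm[cl, ])
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }, numeric(1)))
  }
  true <- rep(classes, each = 20)
  expect_equal(macro_f1(true, true), 1)
  # all-one-class prediction on a balanced set: P = 1/3, R = 1 for that
  # class, 0 elsewhere, so macro F1 = 1/6
  all_tib <- rep("tibial", 60)
  expect_equal(macro_f1(all_tib, true), 1 / 6)
  expect_equal(macro_f1(all_tib, true), oracle(all_tib, true))
  # random predictions agree with the oracle case by case and average 1/3
  set.seed(21)
  sims <- replicate(200, {
    pred <- sample(classes, 60, replace = TRUE)
    f <- macro_f1(pred, true)
    expect_equal(f, oracle(pred, true))
    f
  })
  expect_equal(mean(sims), 1 / 3, tolerance = 0.02)
  expect_error(macro_f1(character(0), character(0)), "non-empty")
})
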
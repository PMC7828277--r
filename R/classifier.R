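PATHWAY_CLASSES <- c("tibial", "peroneal", "sural")

#' Build a pathway classifier
#'
#' Two interchangeable architectures classify 56 x 100 signatures into the
#' three pathways with calibrated softmax probabilities:
#'
#' * `"linear_baseline"`: softmax regression on the flattened signature
#'   (3 x (5600 + 1) parameters), trained by mini-batch Adam. Fast and
#'   deterministic; the default for desk-scale strategy runs.
#' * `"dual_cnn"`: a dual-branch convolutional network. Each branch
#'   processes one channel ordering of the same signature ("spatial
#'   emphasis" = ring-major rows, "temporal emphasis" = longitudinal rows)
#'   through two convolution + average-pooling stages; the branch features
#'   are concatenated into a 3-way softmax head. Branches share topology
#'   but not weights.
#'
#' Initialization is seeded; training continues from the current
#' parameters (warm start) unless the state is rebuilt.
#'
#' @param spec `"linear_baseline"` or `"dual_cnn"`.
#' @param seed Integer seed for parameter initialization.
#' @param hyper Optional list overriding hyperparameters: `lr`, `epochs`,
#'   `batch_size`, and for the CNN `filters` (default `c(8, 16)`) and
#'   `kernel` (default 3).
#' @param input_dim Signature shape (default `c(56, 100)`).
#' @return A `classifier_state`.
#' @export
build_classifier <- function(spec = c("linear_baseline", "dual_cnn"),
                             seed = 1L, hyper = list(),
                             input_dim = c(56L, 100L)) {
  spec <- match.arg(spec)
  defaults <- if (spec == "linear_baseline") {
    list(lr = 0.01, epochs = 8L, batch_size = 256L)
  } else {
    list(lr = 0.003, epochs = 4L, batch_size = 32L,
         filters = c(8L, 16L), kernel = 3L)
  }
  hyper <- utils::modifyList(defaults, hyper)
  params <- with_seed(seed, {
    if (spec == "linear_baseline") {
      d <- prod(input_dim)
      list(W = matrix(stats::rnorm(d * 3, sd = 0.01), d, 3),
           b = numeric(3))
    } else {
      init_dual_cnn_params(input_dim, hyper$filters, hyper$kernel)
    }
  })
  structure(list(
    spec = spec,
    params = params,
    opt = list(m = NULL, v = NULL, t = 0L),
    class_list = PATHWAY_CLASSES,
    input_dim = as.integer(input_dim),
    hyper = hyper,
    history = data.frame(),
    seed = as.integer(seed),
    n_train_calls = 0L
  ), class = "classifier_state")
}

#' @export
print.classifier_state <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<classifier_state> %s, %d parameters, %d training call(s)\n",
              x$spec, np, x$n_train_calls))
  invisible(x)
}

#' Number of trainable parameters
#' @param state A `classifier_state`.
#' @return Integer count.
#' @export
n_parameters <- function(state) {
  sum(vapply(state$params, length, integer(1)))
}

# Extract the model inputs from signatures given as a dataset, an array or
# a list of matrices. Returns the 3-D array (channels x time x N).
as_signature_array <- function(signatures) {
  if (inherits(signatures, "signature_dataset")) {
    return(signatures$signatures)
  }
  if (is.list(signatures)) {
    d <- dim(signatures[[1]])
    return(array(unlist(signatures), dim = c(d, length(signatures))))
  }
  if (length(dim(signatures)) == 2L) {
    return(array(signatures, dim = c(dim(signatures), 1L)))
  }
  signatures
}

#' Train a classifier
#'
#' Mini-batch Adam on the cross-entropy loss; batch order is shuffled with
#' a seed derived from the state's seed and its training-call counter, so
#' repeated runs are bitwise reproducible. Training always continues from
#' the passed-in parameters (warm start); `epochs = 0` returns the state
#' unchanged.
#'
#' Either give `train_folds` (uses the dataset's fold assignment and true
#' labels) or explicit `indices` with `labels` (e.g. a pseudo-labelled
#' subset).
#'
#' @param state A `classifier_state`.
#' @param dataset A `signature_dataset`.
#' @param train_folds Integer fold ids to train on (NULL if using
#'   `indices`).
#' @param epochs Number of passes (default: the state's hyperparameter).
#' @param seed Optional override for the shuffle seed.
#' @param indices Optional explicit signature indices.
#' @param labels Optional labels for `indices` (factor or character).
#' @return The updated `classifier_state`.
#' @export
train <- function(state, dataset, train_folds = NULL, epochs = NULL,
                  seed = NULL, indices = NULL, labels = NULL) {
  stopifnot(inherits(state, "classifier_state"),
            inherits(dataset, "signature_dataset"))
  epochs <- epochs %||% state$hyper$epochs
  if (epochs == 0L) return(state)
  if (is.null(indices)) {
    if (is.null(train_folds) || length(train_folds) == 0L) {
      stop("`train_folds` (or `indices`) must be given", call. = FALSE)
    }
    indices <- fold_indices(dataset, train_folds)
    labels <- dataset$labels[indices]
  }
  labels <- factor(as.character(labels), levels = state$class_list)
  if (length(indices) == 0L) stop("empty training set", call. = FALSE)
  if (any(table(labels) == 0L)) {
    stop("a class is absent from the training data", call. = FALSE)
  }
  arr <- as_signature_array(dataset)[, , indices, drop = FALSE]
  y <- as.integer(labels)
  seed <- seed %||% derive_seed(state$seed,
                                paste0("train/", state$n_train_calls))
  state$n_train_calls <- state$n_train_calls + 1L
  if (state$spec == "linear_baseline") {
    train_linear(state, arr, y, epochs, seed)
  } else {
    train_dual_cnn(state, arr, y, epochs, seed)
  }
}

#' Predict class probabilities
#'
#' Deterministic for fixed parameters. Predicted label is the probability
#' argmax, ties broken toward the lowest class index (tibial < peroneal <
#' sural).
#'
#' @param state A trained `classifier_state`.
#' @param signatures A `signature_dataset`, 3-D array, list of matrices,
#'   or single matrix.
#' @return List with `labels` (factor) and `probabilities` (N x 3 matrix,
#'   rows on the probability simplex).
#' @export
predict_proba <- function(state, signatures) {
  stopifnot(inherits(state, "classifier_state"))
  arr <- as_signature_array(signatures)
  if (!identical(dim(arr)[1:2], state$input_dim)) {
    stop(sprintf("signatures must be %d x %d", state$input_dim[1],
                 state$input_dim[2]), call. = FALSE)
  }
  scores <- if (state$spec == "linear_baseline") {
    linear_scores(state, arr)
  } else {
    dual_cnn_scores(state, arr)
  }
  probs <- softmax_rows(scores)
  colnames(probs) <- state$class_list
  lab_idx <- max.col(probs, ties.method = "first")
  list(
    labels = factor(state$class_list[lab_idx], levels = state$class_list),
    probabilities = probs
  )
}

#' Macro-averaged F1 score
#'
#' Mean over the three classes of `2 P R / (P + R)`, with a class's F1
#' defined as 0 when its precision and recall are both undefined or zero.
#'
#' @param predicted Factor (or character) of predicted labels.
#' @param true Factor (or character) of true labels.
#' @param classes Class levels (default the three pathways).
#' @return Macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(predicted, true, classes = PATHWAY_CLASSES) {
  if (length(predicted) == 0L || length(predicted) != length(true)) {
    stop("`predicted` and `true` must be equal-length and non-empty",
         call. = FALSE)
  }
  predicted <- factor(as.character(predicted), levels = classes)
  true <- factor(as.character(true), levels = classes)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & true == cl)
    fp <- sum(predicted == cl & true != cl)
    fn <- sum(predicted != cl & true == cl)
    denom <- 2 * tp + fp + fn # == P+R scaled; zero iff P and R both zero
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  mean(f1s)
}

# ---- shared internals ----

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(opt$m)) {
    opt$m <- lapply(params, function(p) p * 0)
    opt$v <- lapply(params, function(p) p * 0)
  }
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- linear baseline ----

flatten_signatures <- function(arr) {
  d <- dim(arr)
  t(matrix(arr, d[1] * d[2], d[3]))
}

linear_scores <- function(state, arr) {
  x <- flatten_signatures(arr)
  sweep(x %*% state$params$W, 2L, state$params$b, "+")
}

train_linear <- function(state, arr, y, epochs, seed) {
  x <- flatten_signatures(arr)
  n <- nrow(x)
  yk <- diag(3)[y, , drop = FALSE]
  bs <- min(state$hyper$batch_size, n)
  lr <- state$hyper$lr
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        z <- sweep(xb %*% state$params$W, 2L, state$params$b, "+")
        p <- softmax_rows(z)
        ep_loss <- ep_loss -
          sum(log(pmax(p[cbind(seq_along(idx), y[idx])], 1e-12)))
        d <- (p - yk[idx, , drop = FALSE]) / length(idx)
        grads <- list(W = crossprod(xb, d), b = colSums(d))
        upd <- adam_step(state$params, grads, state$opt, lr)
        state$params <- upd$params
        state$opt <- upd$opt
      }
      losses[ep] <- ep_loss / n
    }
  })
  state$history <- rbind(state$history,
                         data.frame(call = state$n_train_calls,
                                    epoch = seq_len(epochs),
                                    loss = losses))
  state
}
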
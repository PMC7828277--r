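#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from a single master seed and a stage label, so that paired comparisons
#' between strategies consume identical data without any seed bookkeeping by
#' the user.
#'
#' @param master_seed Single integer master seed.
#' @param stage Character label of the stage (e.g. `"dataset/encap/-5"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.finite(master_seed), is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps the result a valid 32-bit integer seed
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
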
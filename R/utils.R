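#' @useDynLib ceRNAdis, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames predict quantile
#' @importFrom utils head read.delim write.table
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) {
  ifelse(x >= 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.2) {
  ifelse(x >= 0, 1, slope)
}

#' Derive a module-specific seed from a global seed
#'
#' Every stochastic operation draws its seed as a deterministic hash of the
#' global seed and an operation label, so modules are independently
#' reproducible: re-running one stage never perturbs another stage's stream.
#'
#' @param seed integer global seed.
#' @param label character operation label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# symmetry check used across similarity/adjacency code
assert_symmetric <- function(m, tol = 1e-9, what = "matrix") {
  if (max(abs(m - Matrix::t(m))) > tol) {
    stop_config("%s is not symmetric within tolerance %g", what, tol)
  }
  invisible(TRUE)
}
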
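#' @keywords internal
"_PACKAGE"

#' @useDynLib afstress, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
#' @importFrom stats approx arima.sim fft glm mvfft plogis predict prcomp
#'   qlogis quantile rbeta rbinom rnorm runif sd var median setNames binomial
#' @importFrom utils head tail write.csv read.csv
NULL

# Derive a reproducible child seed from a parent seed and a tag.
# Keeps results < 2^31 so they are valid R integer seeds.
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(paste0("afstress:", tag))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483629 + 1)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

vec_norm <- function(x) sqrt(rowSums(x^2))

normalize_rows <- function(x) {
  n <- vec_norm(x)
  n[n == 0] <- 1
  x / n
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp to [-1, 1] preserving dimensions (acos-safe dot products)
clamp1 <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}
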
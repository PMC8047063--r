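# Internal numerical helpers shared across the package.

# Numerically stable logistic function.  Two branches avoid overflow of
# exp() for large |x|; both agree analytically with 1/(1+exp(-x)).
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# Stable log(1 + exp(x)); for x > 0 uses x + log1p(exp(-x)).
log1pexp <- function(x) {
  out <- x
  pos <- !is.na(x) & x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Row-normalize a nonnegative square matrix into a transition matrix.
# All-zero rows fall back to the uniform distribution so linear solves
# against (I - a*T) stay well-posed.
row_normalize <- function(A) {
  n <- nrow(A)
  rs <- rowSums(A)
  zero <- rs <= 0
  if (any(zero)) {
    A[zero, ] <- 1 / ncol(A)
    rs[zero] <- 1
  }
  A / rs
}

# Clip negative entries (possible in correlation/cosine networks) to zero;
# transition matrices must be nonnegative.
clip_nonneg <- function(A) {
  A[A < 0] <- 0
  A
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
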
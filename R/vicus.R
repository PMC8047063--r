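# Vicus local spectral operator.
#
# The Vicus matrix Vir = (I - B)' (I - B) is a local alternative to the
# graph Laplacian: row i of B reconstructs node i's (virtual cluster) label
# from its k-nearest-neighbour subnetwork via label diffusion, so the
# quadratic form f' Vir f = sum_i (f_i - sum_j B_ij f_j)^2 penalizes
# functions that are not locally predictable from their neighbourhoods.
# Like the Laplacian, Vir is positive semidefinite and annihilates the
# constant vector (B is row-stochastic).

# k highest-similarity neighbours of node i, excluding i; ties broken by
# ascending index so the neighbourhood is deterministic.
knn_indices <- function(net, i, k) {
  s <- net[i, ]
  s[i] <- -Inf
  order(s, seq_along(s), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(k)]
}

#' Label-diffusion row for one node's local subnetwork
#'
#' Extracts the subnetwork over node \code{i}'s \code{k} nearest
#' neighbours plus \code{i} itself (placed last), row-normalizes it into a
#' transition matrix \eqn{S_i}, and returns the last row of
#' \eqn{(1-\alpha)(I - \alpha S_i)^{-1}} — the terminal state of label
#' propagation started at \code{i}.  The row sums to 1.
#'
#' @param net Square similarity matrix (negatives are clipped to zero).
#' @param i Node index.
#' @param k Neighbourhood size, \code{k < nrow(net)}.
#' @param alpha Diffusion constant in (0,1).
#' @return List with \code{beta} (numeric vector of length \code{k + 1},
#'   neighbours first, self last) and \code{neighbors} (their indices).
#' @export
local_propagation_row <- function(net, i, k, alpha = 0.9) {
  n <- nrow(net)
  if (k >= n) stop("k must be smaller than the number of nodes", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  nb <- knn_indices(net, i, k)
  idx <- c(nb, i)
  P <- clip_nonneg(net[idx, idx, drop = FALSE])
  S <- row_normalize(P)
  m <- k + 1L
  # beta = e_m' (1-alpha) (I - alpha S)^{-1}: one linear solve on the transpose
  beta <- as.numeric(solve(t(diag(m) - alpha * S), (1 - alpha) * diag(m)[, m]))
  list(beta = beta, neighbors = nb)
}

#' Local linear reconstruction matrix B
#'
#' Builds the n-by-n matrix whose row \code{i} expresses node \code{i} as a
#' convex combination of its \code{k} nearest neighbours:
#' \eqn{B_{ij} = \beta_i[j] / (1 - \beta_i[k+1])} for \eqn{j} in the
#' neighbourhood, zero elsewhere.  Every row sums to 1 and the diagonal is
#' zero.
#'
#' @inheritParams local_propagation_row
#' @return n-by-n matrix B.
#' @export
build_B <- function(net, k, alpha = 0.9) {
  net <- as.matrix(net)
  n <- nrow(net)
  if (n != ncol(net)) stop("shape error: network must be square", call. = FALSE)
  B <- matrix(0, n, n, dimnames = dimnames(net))
  for (i in seq_len(n)) {
    lp <- local_propagation_row(net, i, k, alpha)
    self <- lp$beta[k + 1L]
    if (1 - self <= .Machine$double.eps) {
      warning(sprintf("isolated node %d: uniform reconstruction row", i),
              call. = FALSE)
      B[i, lp$neighbors] <- 1 / k
    } else {
      B[i, lp$neighbors] <- lp$beta[seq_len(k)] / (1 - self)
    }
  }
  B
}

#' Vicus local spectral matrix
#'
#' Computes \eqn{Vir = (I - B)^\top (I - B)} from a similarity network.
#' \code{Vir} is positive semidefinite and, because \code{B} is
#' row-stochastic, annihilates constant vectors: \eqn{Vir\,\mathbf{1} = 0}.
#' It is used as a graph-regularization operator in place of the Laplacian,
#' capturing local geometric structure through the k-nearest-neighbour
#' label diffusion.
#'
#' @inheritParams local_propagation_row
#' @return Square matrix with attributes \code{k} and \code{alpha}.
#' @export
vicus_matrix <- function(net, k = min(10L, nrow(net) - 1L), alpha = 0.9) {
  B <- build_B(net, k, alpha)
  IB <- diag(nrow(B)) - B
  Vir <- crossprod(IB)
  dimnames(Vir) <- dimnames(net)
  attr(Vir, "k") <- k
  attr(Vir, "alpha") <- alpha
  Vir
}
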
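#' Random-walk-with-restart diffusion states
#'
#' Computes the diffusion state matrix of a similarity network: row
#' \eqn{i} is the stationary distribution of a random walk that, at each
#' step, restarts at node \eqn{i} with probability \code{restart_prob} and
#' otherwise follows the row-normalized transition matrix.  Solved in
#' closed form, \eqn{D = p\,(I - (1-p)T)^{-1}}.
#'
#' Negative edge weights (possible in correlation networks) are clipped to
#' zero before normalization; all-zero rows fall back to a uniform
#' transition row so the solve is well-posed.
#'
#' @param net Square nonnegative similarity matrix.
#' @param restart_prob Restart probability \eqn{p \in (0,1)}, default 0.5.
#' @return Row-stochastic matrix of diffusion states, same dimnames as
#'   \code{net}, with attribute \code{restart_prob}.
#' @export
rwr_diffusion <- function(net, restart_prob = 0.5) {
  net <- as.matrix(net)
  if (nrow(net) != ncol(net))
    stop("shape error: network must be square", call. = FALSE)
  if (restart_prob <= 0 || restart_prob >= 1)
    stop("restart_prob must be in (0,1)", call. = FALSE)
  Tm <- row_normalize(clip_nonneg(net))
  n <- nrow(Tm)
  D <- restart_prob * solve(diag(n) - (1 - restart_prob) * Tm)
  dimnames(D) <- dimnames(net)
  attr(D, "restart_prob") <- restart_prob
  D
}

#' Fuse similarity networks into a low-dimensional feature matrix
#'
#' Network-fusion embedding in the diffusion component analysis style: for
#' each network compute random-walk-with-restart diffusion states, apply
#' the elementwise transform \eqn{\log(D + 1/n)}, average the transformed
#' matrices across networks, and take the rank-\code{k} SVD of the average,
#' \eqn{\bar A \approx U_k \Sigma_k V_k^\top}.  The returned feature matrix
#' is \eqn{F = U_k \Sigma_k^{1/2}}.
#'
#' The sign of each singular vector pair is fixed so that the
#' largest-magnitude entry of the left vector is positive, which makes the
#' embedding deterministic.
#'
#' @param nets List of square similarity matrices over the same entities
#'   (same order); a single matrix is also accepted.
#' @param k Target dimension, at most the number of entities.
#' @param restart_prob Restart probability for [rwr_diffusion()].
#' @return Entity-by-\code{k} feature matrix; attribute \code{loadings}
#'   holds \eqn{V_k \Sigma_k^{1/2}} so that
#'   \code{F \%*\% t(loadings)} reconstructs the averaged log-diffusion
#'   matrix at full rank.
#' @export
fuse_embed <- function(nets, k, restart_prob = 0.5) {
  if (is.matrix(nets)) nets <- list(nets)
  if (length(nets) == 0L) stop("need at least one network", call. = FALSE)
  n <- nrow(nets[[1L]])
  ids <- rownames(nets[[1L]])
  for (net in nets) {
    if (nrow(net) != n || ncol(net) != n)
      stop("alignment error: networks must share the entity set", call. = FALSE)
    if (!is.null(ids) && !is.null(rownames(net)) &&
        !identical(rownames(net), ids))
      stop("alignment error: network ids disagree", call. = FALSE)
  }
  if (k > n)
    stop(sprintf("dimension error: k = %d exceeds entity count %d", k, n),
         call. = FALSE)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  L <- matrix(0, n, n)
  for (net in nets)
    L <- L + log(rwr_diffusion(net, restart_prob) + 1 / n)
  L <- L / length(nets)
  sv <- svd(L, nu = k, nv = k)
  U <- sv$u
  V <- sv$v
  # deterministic sign: largest-|entry| of each left singular vector positive
  for (j in seq_len(k)) {
    s <- sign(U[which.max(abs(U[, j])), j])
    if (s < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  sq <- sqrt(sv$d[seq_len(k)])
  Fm <- U * rep(sq, each = n)
  rownames(Fm) <- ids
  attr(Fm, "loadings") <- V * rep(sq, each = n)
  attr(Fm, "singular_values") <- sv$d[seq_len(k)]
  Fm
}
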
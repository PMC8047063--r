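#' Neighbourhood smoothing of latent vectors
#'
#' Entities with no observed interaction in \code{Y} have latent vectors
#' learned only from negative pairs, so their representations are
#' unreliable.  Smoothing replaces the latent vector of every such entity
#' by a decayed, similarity-weighted average of the latent vectors of its
#' \code{K} most similar *observed* entities:
#' \deqn{\bar w_i = \frac{1}{Q_i} \sum_{l=1}^{K} \alpha^{l-1}
#'   S(i, d_l)\, w_{d_l}, \qquad
#'   Q_i = \sum_{l=1}^{K} \alpha^{l-1} S(i, d_l),}
#' where \eqn{d_l} is the \eqn{l}-th most similar observed entity and
#' \eqn{\alpha} the decay.  Observed entities pass through unchanged.
#' Negative similarities are clipped to zero in the weights; if every
#' weight clips to zero, the entity keeps its unsmoothed vector (with a
#' warning).
#'
#' @param W,H Latent matrices of the row (n x r) and column (m x r)
#'   entities, e.g. \eqn{W = F^d U}.
#' @param Y Binary association matrix defining which entities are observed
#'   (any 1 in their row/column).
#' @param S_d,S_m Similarity matrices over rows and columns, typically
#'   [cosine_matrix()] of the fused features.
#' @param K Number of observed neighbours to average over (fewer are used
#'   when fewer exist).
#' @param decay Geometric decay \eqn{\alpha \in [0,1]} over the ranked
#'   neighbours.
#' @return List of class \code{"ilmf_smoothed"}: \code{W_bar}, \code{H_bar},
#'   and the observed index sets \code{observed_rows}, \code{observed_cols}.
#' @export
smooth_latents <- function(W, H, Y, S_d, S_m, K = 5L, decay = 0.5) {
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  obs_d <- which(rowSums(Y) > 0)
  obs_m <- which(colSums(Y) > 0)
  if (length(obs_d) == 0L || length(obs_m) == 0L)
    stop("smoothing error: no observed entities in Y", call. = FALSE)
  structure(list(W_bar = smooth_side(W, S_d, obs_d, K, decay),
                 H_bar = smooth_side(H, S_m, obs_m, K, decay),
                 observed_rows = obs_d, observed_cols = obs_m),
            class = "ilmf_smoothed")
}

smooth_side <- function(M, S, observed, K, decay) {
  out <- M
  for (i in setdiff(seq_len(nrow(M)), observed)) {
    sims <- S[i, observed]
    ord <- order(sims, seq_along(sims), decreasing = c(TRUE, FALSE),
                 method = "radix")
    take <- ord[seq_len(min(K, length(observed)))]
    w <- decay^(seq_along(take) - 1L) * pmax(sims[take], 0)
    Q <- sum(w)
    if (Q <= 0) {
      warning(sprintf("entity %d: all smoothing weights zero, kept unsmoothed",
                      i), call. = FALSE)
      next
    }
    out[i, ] <- colSums((w / Q) * M[observed[take], , drop = FALSE])
  }
  out
}

#' Interaction probabilities from smoothed latent vectors
#'
#' Final scoring step: \eqn{\bar P_{ij} = \sigma(\bar w_i \bar h_j^\top)}
#' over the smoothed latent matrices.  When every entity is observed this
#' equals the unsmoothed [probability_matrix()].
#'
#' @param smoothed Result of [smooth_latents()].
#' @return n-by-m matrix of probabilities in (0,1).
#' @export
smoothed_probabilities <- function(smoothed) {
  P <- sigmoid(tcrossprod(smoothed$W_bar, smoothed$H_bar))
  dimnames(P) <- list(rownames(smoothed$W_bar), rownames(smoothed$H_bar))
  P
}
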
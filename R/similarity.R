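#' Gaussian interaction-profile (GIP) kernel
#'
#' Computes the Gaussian interaction-profile kernel between entities from
#' their interaction profiles: entry \eqn{(i,j)} is
#' \eqn{\exp(-\gamma \|p_i - p_j\|^2)}, one profile per row.  The bandwidth
#' is normalized by the mean squared profile norm,
#' \eqn{\gamma = \gamma' / \big(\frac{1}{n}\sum_l \|p_l\|^2\big)}, so the
#' kernel is insensitive to the overall profile density.
#'
#' For a drug-by-metabolite association matrix \code{Y}, drug similarities
#' are \code{gip_kernel(Y)} and metabolite similarities
#' \code{gip_kernel(t(Y))}.  Incidence matrices (e.g. metabolite-by-microbe)
#' are converted to kernels the same way.
#'
#' @param profiles Numeric matrix, one interaction profile per entity row.
#' @param gamma_prime Input bandwidth \eqn{\gamma'}, 1 by default.
#' @return Symmetric kernel matrix with unit diagonal and entries in
#'   \eqn{(0,1]}; the realized bandwidth is attached as attributes
#'   \code{gamma} and \code{gamma_prime}.
#' @examples
#' K <- gip_kernel(rbind(a = c(1, 0), b = c(0, 1)))
#' K["a", "b"]  # exp(-2)
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L)
    stop("gip_kernel: need at least two entities", call. = FALSE)
  stopifnot_finite(profiles, "profiles")
  if (gamma_prime <= 0) stop("gamma_prime must be positive", call. = FALSE)
  sq <- rowSums(profiles^2)
  msq <- mean(sq)
  if (msq <= 0)
    stop("degenerate bandwidth: all interaction profiles are zero",
         call. = FALSE)
  gamma <- gamma_prime / msq
  # ||p_i - p_j||^2 = ||p_i||^2 + ||p_j||^2 - 2 p_i.p_j
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ids <- rownames(profiles)
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  attr(K, "gamma") <- gamma
  attr(K, "gamma_prime") <- gamma_prime
  K
}

#' Cosine similarity matrix of feature rows
#'
#' Pairwise cosine similarity between the rows of a feature matrix.
#'
#' @param F_mat Numeric matrix, one feature vector per entity row; no row
#'   may be all-zero.
#' @return Symmetric matrix of cosines with unit diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @export
cosine_matrix <- function(F_mat) {
  F_mat <- as.matrix(F_mat)
  nrm <- sqrt(rowSums(F_mat^2))
  zero <- nrm <= 0
  if (any(zero)) {
    ids <- rownames(F_mat) %||% as.character(which(zero))
    stop("degenerate row: zero feature vector for entity ",
         paste(ids[zero], collapse = ", "), call. = FALSE)
  }
  S <- tcrossprod(F_mat / nrm)
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  S
}
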
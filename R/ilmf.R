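#' Fit an inductive logistic matrix factorization model
#'
#' End-to-end fit of the Vicus-regularized inductive logistic matrix
#' factorization (ILMF) model to a binary bipartite association matrix.
#' The pipeline is:
#' \enumerate{
#'   \item Build a Gaussian interaction-profile kernel over each entity
#'     class from \code{Y} ([gip_kernel()]), and append any user-supplied
#'     side similarity networks (incidence profiles are first converted to
#'     kernels).
#'   \item Fuse each class's networks into a low-dimensional feature
#'     matrix \eqn{F^d} (n x k1) / \eqn{F^m} (m x k2) by
#'     random-walk-with-restart diffusion plus SVD ([fuse_embed()]).
#'   \item Compute cosine similarities of the features and their Vicus
#'     local spectral matrices ([vicus_matrix()]).
#'   \item Learn projections U (k1 x r), V (k2 x r) by minimizing the
#'     importance-weighted logistic loss with L2 and Vicus penalties using
#'     alternating AdaGrad ([ilmf_train()]).
#'   \item Smooth the latent vectors of entities without observed
#'     interactions over their nearest observed neighbours
#'     ([smooth_latents()]) and score all pairs
#'     ([smoothed_probabilities()]).
#' }
#'
#' @param Y Binary association matrix (rows = drugs / one entity class,
#'   columns = metabolites / the other), with dimnames.  Entries must be
#'   0 or 1.
#' @param drug_nets List of square similarity matrices over the row
#'   entities (e.g. drug-drug correlation), dimnames matching \code{Y}'s
#'   rows.
#' @param met_nets List of square similarity matrices over the column
#'   entities.
#' @param drug_profiles,met_profiles Lists of incidence matrices (one row
#'   per row/column entity of \code{Y}, arbitrary columns, e.g.
#'   metabolite-by-pathway); each is converted to a similarity network via
#'   [gip_kernel()] before fusion.
#' @param config An [ilmf_config()].  Feature dimensions larger than the
#'   entity counts are capped at them.
#' @return An object of class \code{"ilmf"} with components \code{U},
#'   \code{V}, \code{W}, \code{H} (latents), \code{F_d}, \code{F_m},
#'   \code{S_d}, \code{S_m}, \code{Vir_d}, \code{Vir_m}, \code{P} (the
#'   smoothed probability matrix), \code{trace}, \code{objective},
#'   \code{config}, and \code{Y}.
#' @examples
#' sim <- simulate_associations(n_drugs = 20, n_metabolites = 30,
#'                              density_target = 0.15, seed = 1)
#' fit <- ilmf(sim$Y, sim$drug_nets, sim$met_nets,
#'             config = ilmf_config(k2 = 20, max_iter = 50))
#' fit
#' @export
ilmf <- function(Y, drug_nets = list(), met_nets = list(),
                 drug_profiles = list(), met_profiles = list(),
                 config = ilmf_config()) {
  cl <- match.call()
  if (is.null(rownames(Y)))
    rownames(Y) <- paste0("r", seq_len(nrow(Y)))
  if (is.null(colnames(Y)))
    colnames(Y) <- paste0("c", seq_len(ncol(Y)))
  drug_nets <- c(drug_nets,
                 lapply(drug_profiles, gip_kernel, gamma_prime = config$gamma_prime))
  met_nets <- c(met_nets,
                lapply(met_profiles, gip_kernel, gamma_prime = config$gamma_prime))
  al <- align_inputs(Y, drug_nets, met_nets)
  Y <- al$Y
  n <- nrow(Y); m <- ncol(Y)
  if (n < 2L || m < 2L)
    stop("need at least 2 entities on each axis", call. = FALSE)

  cfg <- config
  cfg$k1 <- min(cfg$k1, n)
  cfg$k2 <- min(cfg$k2, m)

  d_kernels <- c(list(gip_kernel(Y, cfg$gamma_prime)), al$drug_nets)
  m_kernels <- c(list(gip_kernel(t(Y), cfg$gamma_prime)), al$met_nets)
  F_d <- fuse_embed(d_kernels, cfg$k1, cfg$rwr_restart)
  F_m <- fuse_embed(m_kernels, cfg$k2, cfg$rwr_restart)
  S_d <- cosine_matrix(F_d)
  S_m <- cosine_matrix(F_m)

  if (cfg$phi > 0) {
    kd <- min(cfg$vicus_k %||% 10L, n - 1L)
    km <- min(cfg$vicus_k %||% 10L, m - 1L)
    Vir_d <- vicus_matrix(S_d, k = kd, alpha = cfg$vicus_alpha)
    Vir_m <- vicus_matrix(S_m, k = km, alpha = cfg$vicus_alpha)
  } else {
    Vir_d <- matrix(0, n, n)
    Vir_m <- matrix(0, m, m)
  }

  fit <- ilmf_train(Y, F_d, F_m, Vir_d, Vir_m, cfg)
  W <- F_d %*% fit$U
  H <- F_m %*% fit$V
  rownames(W) <- rownames(Y); rownames(H) <- colnames(Y)
  sm <- smooth_latents(W, H, Y, S_d, S_m, K = cfg$smooth_K,
                       decay = cfg$smooth_decay)
  P <- smoothed_probabilities(sm)

  structure(list(call = cl, Y = Y, config = cfg,
                 F_d = F_d, F_m = F_m, S_d = S_d, S_m = S_m,
                 Vir_d = Vir_d, Vir_m = Vir_m,
                 U = fit$U, V = fit$V, W = W, H = H,
                 smoothed = sm, P = P,
                 objective = fit$objective, trace = fit$trace,
                 iterations = fit$iterations),
            class = "ilmf")
}

#' @export
print.ilmf <- function(x, ...) {
  cat("Inductive logistic matrix factorization fit\n")
  cat(sprintf("  %d x %d association matrix, %d observed pairs (density %.3f)\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y), mean(x$Y)))
  cat(sprintf("  latent dimension r = %d, features k1 = %d, k2 = %d\n",
              x$config$r, x$config$k1, x$config$k2))
  cat(sprintf("  c = %g, lambda = %g, phi = %g\n",
              x$config$c, x$config$lambda, x$config$phi))
  cat(sprintf("  %d AdaGrad iterations, objective %.4f\n",
              x$iterations, x$objective))
  invisible(x)
}

#' Summarize an ILMF fit
#'
#' Reports fit dimensions, training objective, and in-sample ranking
#' metrics of the smoothed scores against the training associations (these
#' are optimistic; use [cross_validate()] for honest estimates).
#'
#' @param object An \code{"ilmf"} fit.
#' @param ... Unused.
#' @return An object of class \code{"summary.ilmf"}.
#' @export
summary.ilmf <- function(object, ...) {
  met <- rank_metrics(as.vector(object$P), as.vector(object$Y))
  structure(list(fit = object, in_sample = met), class = "summary.ilmf")
}

#' @export
print.summary.ilmf <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  in-sample AUC %.4f, AUPR %.4f, F1-max %.4f (training pairs)\n",
              x$in_sample["auc"], x$in_sample["aupr"], x$in_sample["f1"]))
  invisible(x)
}

#' @export
coef.ilmf <- function(object, ...) {
  list(U = object$U, V = object$V)
}

#' @export
fitted.ilmf <- function(object, ...) object$P

#' @export
residuals.ilmf <- function(object, ...) object$Y - object$P

#' Predicted interaction probabilities
#'
#' Returns the smoothed probability matrix, or the scores of selected
#' pairs.
#'
#' @param object An \code{"ilmf"} fit.
#' @param pairs Optional two-column matrix or data frame of (row, column)
#'   indices or identifiers; if supplied, a vector of their scores is
#'   returned instead of the full matrix.
#' @param ... Unused.
#' @return Probability matrix, or numeric vector when \code{pairs} is
#'   given.
#' @export
predict.ilmf <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(object$P)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
  object$P[pairs]
}

#' @export
plot.ilmf <- function(x, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "l",
                 xlab = "iteration", ylab = "objective",
                 main = "ILMF training objective", ...)
  invisible(x)
}

#' Simulate association matrices from a fitted model
#'
#' Draws binary association matrices with independent Bernoulli entries at
#' the fitted interaction probabilities.
#'
#' @param object An \code{"ilmf"} fit.
#' @param nsim Number of matrices to draw.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of \code{nsim} binary matrices.
#' @export
simulate.ilmf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(k) {
    Yk <- matrix(stats::rbinom(length(object$P), 1, as.vector(object$P)),
                 nrow(object$P), ncol(object$P), dimnames = dimnames(object$P))
    Yk
  })
}
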
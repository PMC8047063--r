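#' Model and pipeline configuration
#'
#' Collects every tunable parameter of the model and its surrounding
#' pipeline, with validation.  Defaults follow the conventions of the
#' logistic matrix factorization literature; see the methods vignette for
#' the rationale behind each choice.
#'
#' @param r Latent dimension of the factorization (>= 1).
#' @param c Importance level (>= 1) up-weighting observed interaction pairs
#'   in the likelihood.
#' @param lambda L2 penalty weight on the projection matrices U and V.
#' @param phi Graph (Vicus) regularization weight.  The default was
#'   selected by the standard grid search on the synthetic benchmark
#'   preset (see the methods vignette).
#' @param k1,k2 Feature dimensions of the fused row-entity (drug) and
#'   column-entity (metabolite) embeddings.
#' @param vicus_k Neighbourhood size for the Vicus operator; \code{NULL}
#'   means \code{min(10, n - 1)} per entity class.
#' @param vicus_alpha Diffusion constant in (0,1) for Vicus label
#'   propagation.
#' @param smooth_K Neighbour count for latent-vector smoothing of entities
#'   without observed interactions.
#' @param smooth_decay Geometric decay in [0,1] applied to successive
#'   smoothing neighbours (distinct from \code{vicus_alpha}).
#' @param rwr_restart Restart probability for random-walk-with-restart
#'   diffusion in network fusion.
#' @param gamma_prime Input bandwidth of the Gaussian interaction-profile
#'   kernel.
#' @param learn_rate AdaGrad base learning rate.
#' @param max_iter Maximum number of alternating AdaGrad iterations.
#' @param tol Relative objective change below which training stops.
#' @param seed RNG seed for the random initialization of U and V.
#' @return A list of class \code{"ilmf_config"}.
#' @export
ilmf_config <- function(r = 8L, c = 2, lambda = 1, phi = 8,
                        k1 = 12L, k2 = 45L,
                        vicus_k = NULL, vicus_alpha = 0.9,
                        smooth_K = 5L, smooth_decay = 0.5,
                        rwr_restart = 0.5, gamma_prime = 1,
                        learn_rate = 0.1, max_iter = 100L,
                        tol = 1e-6, seed = 1L) {
  cfg <- list(r = as.integer(r), c = c, lambda = lambda, phi = phi,
              k1 = as.integer(k1), k2 = as.integer(k2),
              vicus_k = if (is.null(vicus_k)) NULL else as.integer(vicus_k),
              vicus_alpha = vicus_alpha,
              smooth_K = as.integer(smooth_K), smooth_decay = smooth_decay,
              rwr_restart = rwr_restart, gamma_prime = gamma_prime,
              learn_rate = learn_rate, max_iter = as.integer(max_iter),
              tol = tol, seed = as.integer(seed))
  if (cfg$r < 1L) stop("r must be >= 1", call. = FALSE)
  if (cfg$c < 1) stop("c must be >= 1", call. = FALSE)
  if (cfg$lambda < 0 || cfg$phi < 0)
    stop("lambda and phi must be nonnegative", call. = FALSE)
  if (cfg$vicus_alpha <= 0 || cfg$vicus_alpha >= 1)
    stop("vicus_alpha must be in (0,1)", call. = FALSE)
  if (cfg$smooth_decay < 0 || cfg$smooth_decay > 1)
    stop("smooth_decay must be in [0,1]", call. = FALSE)
  if (cfg$rwr_restart <= 0 || cfg$rwr_restart >= 1)
    stop("rwr_restart must be in (0,1)", call. = FALSE)
  if (cfg$smooth_K < 1L) stop("smooth_K must be >= 1", call. = FALSE)
  if (cfg$max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  class(cfg) <- "ilmf_config"
  cfg
}

#' @export
print.ilmf_config <- function(x, ...) {
  cat("ilmf configuration\n")
  flat <- unlist(lapply(x, function(v) if (is.null(v)) "auto" else format(v)))
  cat(paste0("  ", format(names(flat)), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}

# f_ij = F_d[i,] U V' F_m[j,]' : the logit matrix (n x m)
logit_matrix <- function(U, V, F_d, F_m) {
  (F_d %*% U) %*% t(F_m %*% V)
}

#' Interaction probability matrix of a fitted projection pair
#'
#' Applies the logistic function to the inductive logits
#' \eqn{F^d U (F^m V)^\top}: entry \eqn{(i,j)} is the modelled probability
#' that row entity \eqn{i} interacts with column entity \eqn{j}.
#'
#' @param U,V Projection matrices (k1 x r and k2 x r).
#' @param F_d,F_m Feature matrices of the row and column entities
#'   (n x k1 and m x k2).
#' @return n-by-m matrix of probabilities in (0,1).
#' @export
probability_matrix <- function(U, V, F_d, F_m) {
  P <- sigmoid(logit_matrix(U, V, F_d, F_m))
  dimnames(P) <- list(rownames(F_d), rownames(F_m))
  P
}

#' Penalized negative log-likelihood of the inductive LMF model
#'
#' The objective minimized during training: an importance-weighted logistic
#' loss over all pairs, plus L2 penalties on U and V, plus Vicus quadratic
#' penalties on the latent representations \eqn{W = F^d U} and
#' \eqn{H = F^m V},
#' \deqn{\sum_{ij} (1 + c y_{ij} - y_{ij}) \log(1 + e^{f_{ij}})
#'       - c\, y_{ij} f_{ij}
#'       + \tfrac{\lambda}{2}(\|U\|_F^2 + \|V\|_F^2)
#'       + \tfrac{\phi}{2}\big[\mathrm{tr}(W^\top Vir^d W)
#'       + \mathrm{tr}(H^\top Vir^m H)\big].}
#'
#' @param U,V Projection matrices.
#' @param Y Binary association matrix (n x m).
#' @param F_d,F_m Feature matrices.
#' @param Vir_d,Vir_m Vicus matrices of the row and column entity classes.
#' @param c Importance level; \code{lambda}, \code{phi} the penalty weights.
#' @param lambda,phi Regularization weights.
#' @return Scalar objective value.
#' @export
ilmf_objective <- function(U, V, Y, F_d, F_m, Vir_d, Vir_m,
                           c = 2, lambda = 1, phi = 1) {
  if (anyNA(Y) || anyNA(U) || anyNA(V))
    stop("validation error: NaN in inputs", call. = FALSE)
  f <- logit_matrix(U, V, F_d, F_m)
  w <- 1 + c * Y - Y
  data_term <- sum(w * log1pexp(f)) - c * sum(Y * f)
  reg <- lambda / 2 * (sum(U^2) + sum(V^2))
  graph <- 0
  if (phi != 0) {
    W <- F_d %*% U
    H <- F_m %*% V
    graph <- phi / 2 * (sum(W * (Vir_d %*% W)) + sum(H * (Vir_m %*% H)))
  }
  data_term + reg + graph
}

#' Analytic gradients of the training objective
#'
#' Gradient of [ilmf_objective()] with respect to U and V:
#' \eqn{\nabla_U = F^{d\top}[(1 + cY - Y)\odot P - cY]F^m V + \lambda U +
#' \phi F^{d\top} Vir^d F^d U}, and symmetrically for V.
#'
#' @inheritParams ilmf_objective
#' @return List with elements \code{dU} (k1 x r) and \code{dV} (k2 x r).
#' @export
ilmf_gradients <- function(U, V, Y, F_d, F_m, Vir_d, Vir_m,
                           c = 2, lambda = 1, phi = 1) {
  P <- sigmoid(logit_matrix(U, V, F_d, F_m))
  R <- (1 + c * Y - Y) * P - c * Y      # d loss / d f
  FdU <- F_d %*% U
  FmV <- F_m %*% V
  dU <- crossprod(F_d, R %*% FmV) + lambda * U
  dV <- crossprod(F_m, crossprod(R, FdU)) + lambda * V
  if (phi != 0) {
    dU <- dU + phi * crossprod(F_d, Vir_d %*% FdU)
    dV <- dV + phi * crossprod(F_m, Vir_m %*% FmV)
  }
  list(dU = dU, dV = dV)
}

#' Train the inductive LMF model by alternating AdaGrad
#'
#' Minimizes [ilmf_objective()] by alternating adaptive-gradient descent:
#' each iteration updates U with V fixed, then V with the new U, with
#' per-parameter step sizes
#' \eqn{\eta / \sqrt{\sum_t g_t^2 + 10^{-8}}}.  U and V are initialized
#' i.i.d. normal with standard deviation \eqn{1/\sqrt{r}} from
#' \code{config$seed}.  Training stops at \code{max_iter} or when the
#' relative objective change drops below \code{config$tol}; the parameters
#' with the lowest recorded objective are returned.
#'
#' @param Y Binary association matrix.
#' @param F_d,F_m Feature matrices of the two entity classes.
#' @param Vir_d,Vir_m Vicus matrices (may be zero matrices when
#'   \code{phi = 0}).
#' @param config An [ilmf_config()].
#' @return List with \code{U}, \code{V}, \code{objective} (the best value),
#'   \code{trace} (objective per iteration, element 1 = initial value) and
#'   \code{iterations}.
#' @export
ilmf_train <- function(Y, F_d, F_m, Vir_d, Vir_m, config = ilmf_config()) {
  k1 <- ncol(F_d); k2 <- ncol(F_m); r <- config$r
  if (nrow(F_d) != nrow(Y) || nrow(F_m) != ncol(Y))
    stop("shape error: feature matrices must match the association matrix",
         call. = FALSE)
  set.seed(config$seed)
  U <- matrix(stats::rnorm(k1 * r, sd = 1 / sqrt(r)), k1, r)
  V <- matrix(stats::rnorm(k2 * r, sd = 1 / sqrt(r)), k2, r)
  GU <- matrix(0, k1, r)
  GV <- matrix(0, k2, r)
  c0 <- config$c; lambda <- config$lambda; phi <- config$phi
  eta <- config$learn_rate
  obj <- ilmf_objective(U, V, Y, F_d, F_m, Vir_d, Vir_m, c0, lambda, phi)
  trace <- numeric(config$max_iter + 1L)
  trace[1L] <- obj
  best <- list(U = U, V = V, objective = obj)
  it <- 0L
  for (t in seq_len(config$max_iter)) {
    g <- ilmf_gradients(U, V, Y, F_d, F_m, Vir_d, Vir_m, c0, lambda, phi)$dU
    GU <- GU + g^2
    U <- U - eta * g / sqrt(GU + 1e-8)
    g <- ilmf_gradients(U, V, Y, F_d, F_m, Vir_d, Vir_m, c0, lambda, phi)$dV
    GV <- GV + g^2
    V <- V - eta * g / sqrt(GV + 1e-8)
    new_obj <- ilmf_objective(U, V, Y, F_d, F_m, Vir_d, Vir_m, c0, lambda, phi)
    if (!is.finite(new_obj))
      stop(sprintf("training error: objective diverged at iteration %d", t),
           call. = FALSE)
    it <- t
    trace[t + 1L] <- new_obj
    if (new_obj < best$objective)
      best <- list(U = U, V = V, objective = new_obj)
    if (abs(new_obj - obj) / max(abs(obj), .Machine$double.eps) < config$tol) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  rownames(best$U) <- colnames(F_d)
  rownames(best$V) <- colnames(F_m)
  list(U = best$U, V = best$V, objective = best$objective,
       trace = trace[seq_len(it + 1L)], iterations = it)
}
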
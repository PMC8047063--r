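#' Stratified fold plan for repeated pair-wise cross-validation
#'
#' Randomly divides the observed (1) and unobserved (0) pairs of the
#' association matrix each into \code{n_folds} near-equal parts, repeated
#' \code{n_repeats} times, so that every fold's test set contains both
#' classes in proportion.  Within a repeat the test sets partition all
#' \eqn{n \times m} pairs.
#'
#' @param Y Binary association matrix.
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Number of repeats (default 5).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return Object of class \code{"ilmf_folds"}: a list of repeats, each a
#'   list of integer vectors of linear pair indices into \code{Y}.
#' @export
make_folds <- function(Y, n_folds = 5L, n_repeats = 5L, seed = 1L) {
  pos <- which(Y == 1)
  neg <- which(Y == 0)
  if (length(pos) < n_folds || length(neg) < n_folds)
    stop(sprintf("fold error: need at least %d pairs of each class", n_folds),
         call. = FALSE)
  set.seed(seed)
  repeats <- lapply(seq_len(n_repeats), function(rep) {
    p <- sample(pos)
    q <- sample(neg)
    pa <- rep_len(seq_len(n_folds), length(p))
    qa <- rep_len(seq_len(n_folds), length(q))
    lapply(seq_len(n_folds), function(f) sort(c(p[pa == f], q[qa == f])))
  })
  structure(list(repeats = repeats, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 dim = dim(Y)),
            class = "ilmf_folds")
}

#' @export
print.ilmf_folds <- function(x, ...) {
  cat(sprintf("fold plan: %d repeats x %d folds over a %d x %d matrix (seed %d)\n",
              x$n_repeats, x$n_folds, x$dim[1], x$dim[2], x$seed))
  invisible(x)
}

#' Ranking metrics: AUC, AUPR and maximum F1
#'
#' AUC is the rank statistic (probability that a random positive outscores
#' a random negative, ties counted half).  AUPR is the area under the
#' precision-recall curve in average-precision form (step-wise, no
#' trapezoidal interpolation).  F1 is the maximum F1 over all score
#' thresholds ("F1-max"), since no single operating threshold is
#' canonical.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Binary vector (0/1) of the same length; both classes must
#'   be present.
#' @return Named numeric vector \code{c(auc, aupr, f1)}.
#' @export
rank_metrics <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels <- as.numeric(labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("metric error: both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(which(diff(s) != 0), length(s))  # last index at each threshold
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / P
  aupr <- sum(diff(c(0, rec)) * prec)
  f1 <- max(ifelse(tp > 0, 2 * prec * rec / (prec + rec), 0))
  c(auc = auc, aupr = aupr, f1 = f1)
}

#' Repeated cross-validation of the full ILMF pipeline
#'
#' For every fold, the held-out positive pairs are zeroed in a training
#' copy of \code{Y} and the *entire* pipeline — interaction-profile
#' kernels, network fusion, Vicus matrices, training, smoothing — is
#' recomputed from the training matrix only, so no information about the
#' held-out pairs leaks into the features.  Held-out pairs are then scored
#' with the smoothed probabilities and AUC/AUPR/F1 computed per fold.
#'
#' @param Y Binary association matrix.
#' @param drug_nets,met_nets Optional side similarity networks (external
#'   to \code{Y}, used as-is in every fold).
#' @param config An [ilmf_config()].
#' @param plan A fold plan from [make_folds()]; defaults to 5x5 with
#'   \code{config$seed}.
#' @param verbose Print per-fold progress.
#' @return Object of class \code{"ilmf_cv"}: data frame \code{folds}
#'   (repeat, fold, auc, aupr, f1), \code{repeat_means}, and \code{summary}
#'   (mean and sd over repeats of the per-repeat means).
#' @export
cross_validate <- function(Y, drug_nets = list(), met_nets = list(),
                           config = ilmf_config(), plan = NULL,
                           verbose = FALSE) {
  if (is.null(plan)) plan <- make_folds(Y, seed = config$seed)
  rows <- list()
  for (rep_i in seq_along(plan$repeats)) {
    folds <- plan$repeats[[rep_i]]
    for (fold_i in seq_along(folds)) {
      test_idx <- folds[[fold_i]]
      Y_train <- Y
      Y_train[test_idx] <- 0
      fit <- ilmf(Y_train, drug_nets = drug_nets, met_nets = met_nets,
                  config = config)
      met <- rank_metrics(fit$P[test_idx], Y[test_idx])
      rows[[length(rows) + 1L]] <-
        data.frame(rep = rep_i, fold = fold_i,
                   auc = met["auc"], aupr = met["aupr"], f1 = met["f1"],
                   row.names = NULL)
      if (verbose)
        message(sprintf("repeat %d fold %d: AUC %.4f AUPR %.4f F1 %.4f",
                        rep_i, fold_i, met["auc"], met["aupr"], met["f1"]))
    }
  }
  folds_df <- do.call(rbind, rows)
  rm_df <- stats::aggregate(cbind(auc, aupr, f1) ~ rep, folds_df, mean)
  structure(list(folds = folds_df, repeat_means = rm_df,
                 summary = list(mean = colMeans(rm_df[, c("auc", "aupr", "f1")]),
                                sd = apply(rm_df[, c("auc", "aupr", "f1")], 2,
                                           stats::sd)),
                 config = config, plan_seed = plan$seed),
            class = "ilmf_cv")
}

#' @export
print.ilmf_cv <- function(x, ...) {
  m <- x$summary$mean; s <- x$summary$sd
  cat(sprintf("cross-validation over %d repeats x %d folds\n",
              max(x$folds$rep), max(x$folds$fold)))
  cat(sprintf("  AUC  %.4f (sd %.4f)\n  AUPR %.4f (sd %.4f)\n  F1   %.4f (sd %.4f)\n",
              m["auc"], s["auc"], m["aupr"], s["aupr"], m["f1"], s["f1"]))
  invisible(x)
}

#' Grid search over model hyperparameters
#'
#' Exhaustively evaluates the Cartesian grid of (lambda, phi, c, r) by
#' [cross_validate()] and returns the configuration maximizing mean AUPR
#' (ties broken by AUC, then by smaller r), plus the full score table.
#' The default grids follow the customary ranges
#' \eqn{\lambda, \phi \in \{2^{-3}, \dots, 2^3\}}, \eqn{r \in \{5,\dots,12\}},
#' \eqn{c \in \{2,\dots,8\}}; cells are evaluated in deterministic order.
#'
#' @param Y,drug_nets,met_nets,plan As in [cross_validate()].
#' @param lambda_grid,phi_grid,c_grid,r_grid Numeric grids.
#' @param config Base configuration supplying all other fields.
#' @param verbose Print one line per cell.
#' @return List with \code{best_config}, \code{best_scores}, and
#'   \code{table} (a data frame of lambda, phi, c, r, auc, aupr, f1).
#' @export
grid_search <- function(Y, drug_nets = list(), met_nets = list(),
                        plan = NULL,
                        lambda_grid = 2^(-3:3), phi_grid = 2^(-3:3),
                        c_grid = 2:8, r_grid = 5:12,
                        config = ilmf_config(), verbose = FALSE) {
  if (length(lambda_grid) == 0L || length(phi_grid) == 0L ||
      length(c_grid) == 0L || length(r_grid) == 0L)
    stop("grids must be nonempty", call. = FALSE)
  if (is.null(plan)) plan <- make_folds(Y, seed = config$seed)
  cells <- expand.grid(lambda = lambda_grid, phi = phi_grid,
                       c = c_grid, r = r_grid)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$lambda <- cells$lambda[i]; cfg$phi <- cells$phi[i]
    cfg$c <- cells$c[i]; cfg$r <- as.integer(cells$r[i])
    cv <- cross_validate(Y, drug_nets, met_nets, config = cfg, plan = plan)
    res[[i]] <- cv$summary$mean
    if (verbose)
      message(sprintf("lambda=%g phi=%g c=%g r=%d: AUPR %.4f AUC %.4f",
                      cfg$lambda, cfg$phi, cfg$c, cfg$r,
                      res[[i]]["aupr"], res[[i]]["auc"]))
  }
  tab <- cbind(cells, do.call(rbind, res))
  ord <- order(-tab$aupr, -tab$auc, tab$r)
  best <- tab[ord[1L], ]
  best_cfg <- config
  best_cfg$lambda <- best$lambda; best_cfg$phi <- best$phi
  best_cfg$c <- best$c; best_cfg$r <- as.integer(best$r)
  list(best_config = best_cfg,
       best_scores = c(auc = best$auc, aupr = best$aupr, f1 = best$f1),
       table = tab)
}

#' Rank unobserved pairs by predicted score
#'
#' Sorts the pairs with \eqn{y_{ij} = 0} by predicted score, descending
#' (ties broken by row then column index), and returns the top of the
#' list — the model's novel-association candidates.
#'
#' @param Y Binary association matrix.
#' @param P Score matrix of the same shape.
#' @param top_k Number of pairs to return; truncated (with a warning) if
#'   it exceeds the number of unobserved pairs.
#' @return Data frame with columns \code{drug}, \code{metabolite} (ids or
#'   indices), \code{row}, \code{col}, \code{score}.
#' @export
rank_novel <- function(Y, P, top_k = 20L) {
  if (!all(dim(Y) == dim(P)))
    stop("shape error: Y and P must have the same dimensions", call. = FALSE)
  idx <- which(Y == 0)
  if (top_k > length(idx)) {
    warning(sprintf("only %d unobserved pairs available", length(idx)),
            call. = FALSE)
    top_k <- length(idx)
  }
  if (top_k == 0L)
    return(data.frame(drug = character(0), metabolite = character(0),
                      row = integer(0), col = integer(0), score = numeric(0)))
  ri <- (idx - 1L) %% nrow(Y) + 1L
  ci <- (idx - 1L) %/% nrow(Y) + 1L
  o <- order(-P[idx], ri, ci)[seq_len(top_k)]
  data.frame(
    drug = (rownames(Y) %||% as.character(seq_len(nrow(Y))))[ri[o]],
    metabolite = (colnames(Y) %||% as.character(seq_len(ncol(Y))))[ci[o]],
    row = ri[o], col = ci[o], score = P[idx][o],
    row.names = NULL)
}
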
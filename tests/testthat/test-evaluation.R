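test_that("fold plans are stratified partitions of all pairs", {
  Y <- rand_assoc(8, 10, density = 0.3, seed = 1)
  plan <- make_folds(Y, n_folds = 5, n_repeats = 3, seed = 7)
  P <- sum(Y); N <- length(Y) - P
  for (rep_folds in plan$repeats) {
    all_idx <- sort(unlist(rep_folds))
    expect_identical(all_idx, seq_along(Y))              # partition
    expect_identical(anyDuplicated(unlist(rep_folds)), 0L)
    for (fold in rep_folds) {
      np <- sum(Y[fold] == 1)
      nn <- sum(Y[fold] == 0)
      expect_true(np %in% c(floor(P / 5), ceiling(P / 5)))
      expect_true(nn %in% c(floor(N / 5), ceiling(N / 5)))
    }
  }
})

test_that("fold plans are deterministic in the seed", {
  Y <- rand_assoc(8, 10, seed = 2)
  expect_identical(make_folds(Y, seed = 5), make_folds(Y, seed = 5))
  expect_false(identical(make_folds(Y, seed = 5)$repeats,
                         make_folds(Y, seed = 6)$repeats))
  expect_error(make_folds(matrix(0:1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))),
               "fold error")
})

test_that("perfectly separating scores give perfect metrics", {
  met <- rank_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(met), c(1, 1, 1))
})

test_that("AUC equals the pairwise concordance oracle, ties included", {
  for (seed in 1:20) {
    set.seed(seed)
    labels <- rbinom(20, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, by = 0.25), 20, replace = TRUE)  # forces ties
    met <- rank_metrics(scores, labels)
    expect_equal(unname(met["auc"]), concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(3)
  labels <- rbinom(4000, 1, 0.5)
  scores <- runif(4000)
  expect_equal(unname(rank_metrics(scores, labels)["auc"]), 0.5,
               tolerance = 0.05)
})

test_that("AUPR is the average-precision step sum", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  labels <- c(1, 0, 1, 0)
  # precision at the two positive hits: 1/1 and 2/3, each covering recall 1/2
  expect_equal(unname(rank_metrics(scores, labels)["aupr"]),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_error(rank_metrics(c(1, 2), c(1, 1)), "both classes")
})

test_that("cross-validation is deterministic and leakage-free by construction", {
  sim <- simulate_associations(n_drugs = 14, n_metabolites = 18,
                               density_target = 0.2, seed = 4)
  cfg <- tiny_config()
  plan <- make_folds(sim$Y, n_folds = 3, n_repeats = 1, seed = 9)
  cv1 <- cross_validate(sim$Y, sim$drug_nets, sim$met_nets, cfg, plan)
  cv2 <- cross_validate(sim$Y, sim$drug_nets, sim$met_nets, cfg, plan)
  expect_identical(cv1$folds, cv2$folds)
  expect_true(all(cv1$folds$auc >= 0 & cv1$folds$auc <= 1))
  # replay one fold by hand: zeroed held-out positives, full refit
  idx <- plan$repeats[[1]][[2]]
  Y_train <- sim$Y; Y_train[idx] <- 0
  fit <- ilmf(Y_train, sim$drug_nets, sim$met_nets, config = cfg)
  expect_false(any(fit$Y[idx] == 1))   # no held-out positive enters training
  met <- rank_metrics(fit$P[idx], sim$Y[idx])
  expect_equal(as.numeric(cv1$folds[cv1$folds$fold == 2, c("auc", "aupr", "f1")]),
               unname(met), tolerance = 1e-12)
})

test_that("planted structure is recovered better than a permuted null", {
  sim <- simulate_associations(n_drugs = 16, n_metabolites = 20,
                               density_target = 0.2, true_rank = 2,
                               noise_sd = 0.05, seed = 5)
  cfg <- tiny_config(phi = 8)
  plan <- make_folds(sim$Y, n_folds = 3, n_repeats = 1, seed = 10)
  cv <- cross_validate(sim$Y, sim$drug_nets, sim$met_nets, cfg, plan)
  set.seed(11)
  Y_null <- matrix(sample(as.vector(sim$Y)), nrow(sim$Y), ncol(sim$Y),
                   dimnames = dimnames(sim$Y))
  cv_null <- cross_validate(Y_null, sim$drug_nets, sim$met_nets, cfg,
                            make_folds(Y_null, 3, 1, seed = 10))
  expect_gt(cv$summary$mean["auc"], cv_null$summary$mean["auc"])
})

test_that("a singleton grid reproduces a single cross-validation", {
  sim <- simulate_associations(n_drugs = 12, n_metabolites = 15,
                               density_target = 0.2, seed = 6)
  cfg <- tiny_config()
  plan <- make_folds(sim$Y, n_folds = 3, n_repeats = 1, seed = 12)
  gs <- grid_search(sim$Y, sim$drug_nets, sim$met_nets, plan = plan,
                    lambda_grid = 1, phi_grid = 2, c_grid = 2, r_grid = 3,
                    config = cfg)
  cfg2 <- cfg; cfg2$lambda <- 1; cfg2$phi <- 2; cfg2$c <- 2; cfg2$r <- 3L
  cv <- cross_validate(sim$Y, sim$drug_nets, sim$met_nets, cfg2, plan)
  expect_equal(unname(gs$best_scores["aupr"]),
               unname(cv$summary$mean["aupr"]), tolerance = 1e-12)
  expect_equal(nrow(gs$table), 1L)
  expect_error(grid_search(sim$Y, plan = plan, lambda_grid = numeric(0)),
               "nonempty")
})

test_that("novel-pair ranking equals a full sort of the masked scores", {
  set.seed(13)
  Y <- rand_assoc(6, 7, density = 0.3, seed = 13)
  P <- matrix(runif(42), 6, 7)
  P[2, 3] <- P[4, 5] <- 0.777   # force score ties
  top <- rank_novel(Y, P, top_k = 10)
  zeros <- which(Y == 0)
  ri <- (zeros - 1) %% 6 + 1; ci <- (zeros - 1) %/% 6 + 1
  ord <- order(-P[zeros], ri, ci)
  expect_equal(top$score, P[zeros][ord][1:10])
  expect_equal(top$row, ri[ord][1:10], ignore_attr = TRUE)
  expect_equal(top$col, ci[ord][1:10], ignore_attr = TRUE)
  # truncation and the all-known edge case
  expect_warning(full <- rank_novel(Y, P, top_k = 10000), "unobserved")
  expect_identical(nrow(full), length(zeros))
  expect_identical(nrow(suppressWarnings(rank_novel(matrix(1, 2, 2), matrix(0.5, 2, 2), 5))), 0L)
})
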
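# small random model instance shared by the core tests
core_instance <- function(n = 6, m = 5, k1 = 4, k2 = 3, r = 2, seed = 1) {
  set.seed(seed)
  list(Y = matrix(rbinom(n * m, 1, 0.3), n, m),
       F_d = matrix(rnorm(n * k1), n, k1),
       F_m = matrix(rnorm(m * k2), m, k2),
       U = matrix(rnorm(k1 * r), k1, r),
       V = matrix(rnorm(k2 * r), k2, r),
       Vir_d = vicus_matrix(rand_similarity_net(n, seed = seed), k = 3),
       Vir_m = vicus_matrix(rand_similarity_net(m, seed = seed + 1), k = 3))
}

test_that("zero projections give probability one half everywhere", {
  inst <- core_instance()
  P <- probability_matrix(0 * inst$U, inst$V, inst$F_d, inst$F_m)
  expect_equal(unname(P), matrix(0.5, 6, 5))
})

test_that("probabilities agree with the scalar logistic loop", {
  inst <- core_instance(seed = 2)
  P <- probability_matrix(inst$U, inst$V, inst$F_d, inst$F_m)
  W <- inst$F_d %*% inst$U
  H <- inst$F_m %*% inst$V
  for (i in 1:6) for (j in 1:5) {
    x <- sum(W[i, ] * H[j, ])
    expect_equal(P[i, j], exp(x) / (1 + exp(x)), tolerance = 1e-12)
  }
  expect_true(all(P > 0 & P < 1))
})

test_that("negating U reflects the probabilities around one half", {
  inst <- core_instance(seed = 3)
  P <- probability_matrix(inst$U, inst$V, inst$F_d, inst$F_m)
  Pn <- probability_matrix(-inst$U, inst$V, inst$F_d, inst$F_m)
  expect_equal(Pn, 1 - P, tolerance = 1e-12)
})

test_that("objective at zero parameters has the closed form", {
  inst <- core_instance(seed = 4)
  for (c0 in c(1, 2, 5)) {
    obj <- ilmf_objective(0 * inst$U, 0 * inst$V, inst$Y, inst$F_d, inst$F_m,
                          inst$Vir_d, inst$Vir_m, c = c0, lambda = 3, phi = 7)
    expect_equal(obj, sum((1 + c0 * inst$Y - inst$Y) * log(2)),
                 tolerance = 1e-12)
  }
})

test_that("vectorized objective equals the literal double-loop transcription", {
  for (seed in 1:3) {
    inst <- core_instance(seed = seed + 10)
    for (c0 in c(1, 2, 5)) for (lam in c(0, 1)) for (phi in c(0, 1)) {
      expect_equal(
        ilmf_objective(inst$U, inst$V, inst$Y, inst$F_d, inst$F_m,
                       inst$Vir_d, inst$Vir_m, c = c0, lambda = lam, phi = phi),
        naive_objective(inst$U, inst$V, inst$Y, inst$F_d, inst$F_m,
                        inst$Vir_d, inst$Vir_m, c = c0, lambda = lam, phi = phi),
        tolerance = 1e-10)
    }
  }
})

test_that("c = 1 collapses the data term to the unweighted logistic loss", {
  inst <- core_instance(seed = 5)
  f <- (inst$F_d %*% inst$U) %*% t(inst$F_m %*% inst$V)
  expect_equal(
    ilmf_objective(inst$U, inst$V, inst$Y, inst$F_d, inst$F_m,
                   inst$Vir_d, inst$Vir_m, c = 1, lambda = 0, phi = 0),
    sum(log(1 + exp(f)) - inst$Y * f), tolerance = 1e-10)
})

test_that("increasing c increases the data term when positives are present", {
  inst <- core_instance(seed = 6)
  vals <- vapply(c(1, 2, 4, 8), function(c0)
    ilmf_objective(inst$U, inst$V, inst$Y, inst$F_d, inst$F_m,
                   inst$Vir_d, inst$Vir_m, c = c0, lambda = 0, phi = 0),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("analytic gradients match central finite differences", {
  inst <- core_instance(seed = 7)
  h <- 1e-6
  for (pt in 1:5) {
    set.seed(100 + pt)
    U <- matrix(rnorm(length(inst$U), sd = 0.5), nrow(inst$U))
    V <- matrix(rnorm(length(inst$V), sd = 0.5), nrow(inst$V))
    g <- ilmf_gradients(U, V, inst$Y, inst$F_d, inst$F_m,
                        inst$Vir_d, inst$Vir_m, c = 2, lambda = 1, phi = 1)
    obj <- function(U, V) ilmf_objective(U, V, inst$Y, inst$F_d, inst$F_m,
                                         inst$Vir_d, inst$Vir_m,
                                         c = 2, lambda = 1, phi = 1)
    fd_U <- matrix(0, nrow(U), ncol(U))
    for (a in seq_along(U)) {
      Up <- U; Um <- U
      Up[a] <- Up[a] + h; Um[a] <- Um[a] - h
      fd_U[a] <- (obj(Up, V) - obj(Um, V)) / (2 * h)
    }
    fd_V <- matrix(0, nrow(V), ncol(V))
    for (a in seq_along(V)) {
      Vp <- V; Vm <- V
      Vp[a] <- Vp[a] + h; Vm[a] <- Vm[a] - h
      fd_V[a] <- (obj(U, Vp) - obj(U, Vm)) / (2 * h)
    }
    expect_lt(max(abs(g$dU - fd_U)) / max(abs(fd_U)), 1e-5)
    expect_lt(max(abs(g$dV - fd_V)) / max(abs(fd_V)), 1e-5)
  }
})

test_that("the objective is invariant under joint orthogonal rotation of U and V", {
  inst <- core_instance(seed = 8, r = 3)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta),  cos(theta), 0),
             c(0, 0, 1))
  expect_equal(
    ilmf_objective(inst$U %*% R, inst$V %*% R, inst$Y, inst$F_d, inst$F_m,
                   inst$Vir_d, inst$Vir_m, c = 2, lambda = 1, phi = 1),
    ilmf_objective(inst$U, inst$V, inst$Y, inst$F_d, inst$F_m,
                   inst$Vir_d, inst$Vir_m, c = 2, lambda = 1, phi = 1),
    tolerance = 1e-8)
})

test_that("training descends and is bit-identical under a fixed seed", {
  for (seed in 1:5) {
    inst <- core_instance(n = 8, m = 10, seed = seed + 30)
    cfg <- ilmf_config(r = 2, k1 = 4, k2 = 3, max_iter = 40, seed = seed)
    fit <- ilmf_train(inst$Y, inst$F_d, inst$F_m, inst$Vir_d, inst$Vir_m, cfg)
    expect_lte(fit$trace[length(fit$trace)], fit$trace[1])
    expect_lte(fit$objective, min(fit$trace) + 1e-12)
    fit2 <- ilmf_train(inst$Y, inst$F_d, inst$F_m, inst$Vir_d, inst$Vir_m, cfg)
    expect_identical(fit$U, fit2$U)
    expect_identical(fit$V, fit2$V)
  }
})

test_that("training on a planted logit model beats chance on held-out pairs", {
  set.seed(9)
  n <- 12; m <- 14; r <- 2
  A <- matrix(rnorm(n * r, sd = 1.5), n, r)
  B <- matrix(rnorm(m * r, sd = 1.5), m, r)
  P_true <- 1 / (1 + exp(-tcrossprod(A, B)))
  Y <- matrix(rbinom(n * m, 1, P_true), n, m)
  held <- sample(n * m, 40)
  Y_train <- Y; Y_train[held] <- 0
  if (length(unique(Y[held])) < 2) skip("degenerate draw")
  fit <- ilmf_train(Y_train, A, B, matrix(0, n, n), matrix(0, m, m),
                    ilmf_config(r = r, k1 = r, k2 = r, c = 2, lambda = 0,
                                phi = 0, max_iter = 100, seed = 2))
  P_hat <- probability_matrix(fit$U, fit$V, A, B)
  expect_gt(rank_metrics(P_hat[held], Y[held])["auc"], 0.5)
})

test_that("training reports divergence instead of silently failing", {
  inst <- core_instance(seed = 10)
  cfg <- ilmf_config(r = 2, learn_rate = 1e6, max_iter = 50, seed = 1)
  expect_error(
    ilmf_train(inst$Y, 1e200 * inst$F_d, 1e200 * inst$F_m,
               inst$Vir_d, inst$Vir_m, cfg),
    "diverged|NaN")
})
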
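# Shared fixture builders; everything is generated in code under fixed seeds.

# random labelled matrix with unique ids
rand_labeled_matrix <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(round(rnorm(n * m), 6), n, m,
         dimnames = list(paste0("row", seq_len(n)), paste0("col", seq_len(m))))
}

# random symmetric similarity network with unit diagonal
rand_similarity_net <- function(n, seed = 1, ids = paste0("e", seq_len(n))) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  S <- (A + t(A)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

# random binary association matrix guaranteed to have both classes and at
# least one positive per axis overall
rand_assoc <- function(n, m, density = 0.25, seed = 1) {
  set.seed(seed)
  Y <- matrix(rbinom(n * m, 1, density), n, m,
              dimnames = list(paste0("d", seq_len(n)), paste0("t", seq_len(m))))
  if (sum(Y) == 0) Y[1, 1] <- 1
  if (sum(Y) == length(Y)) Y[n, m] <- 0
  Y
}

# small fast configuration for pipeline tests on tiny matrices
tiny_config <- function(...) {
  ilmf_config(r = 3, k1 = 4, k2 = 5, max_iter = 30, vicus_k = 3, ...)
}

# independent scalar-loop objective: literal transcription of the
# penalized weighted logistic loss, used as the oracle for the vectorized
# implementation
naive_objective <- function(U, V, Y, F_d, F_m, Vir_d, Vir_m, c, lambda, phi) {
  n <- nrow(Y); m <- ncol(Y)
  W <- F_d %*% U
  H <- F_m %*% V
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    f <- sum(W[i, ] * H[j, ])
    y <- Y[i, j]
    total <- total + (1 + c * y - y) * log(1 + exp(f)) - c * y * f
  }
  total <- total + lambda / 2 * (sum(U^2) + sum(V^2))
  g <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) g <- g + sum(W[a, ] * W[b, ]) * Vir_d[a, b]
  for (a in seq_len(m)) for (b in seq_len(m)) g <- g + sum(H[a, ] * H[b, ]) * Vir_m[a, b]
  total + phi / 2 * g
}

# brute-force AUC: fraction of concordant (positive, negative) pairs with
# half credit for ties
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# literal per-entity transcription of the neighbourhood-smoothing rule
naive_smooth <- function(M, S, Y_margin, K, decay) {
  observed <- which(Y_margin > 0)
  out <- M
  for (i in seq_len(nrow(M))) {
    if (i %in% observed) next
    sims <- S[i, observed]
    ord <- order(-sims, seq_along(sims))
    take <- ord[seq_len(min(K, length(observed)))]
    Q <- 0; acc <- rep(0, ncol(M))
    for (l in seq_along(take)) {
      mu <- decay^(l - 1) * max(S[i, observed[take[l]]], 0)
      Q <- Q + mu
      acc <- acc + mu * M[observed[take[l]], ]
    }
    if (Q > 0) out[i, ] <- acc / Q
  }
  out
}
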
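# Shared fixtures and independent oracles.

# Small deterministic feature table: k case + k control samples, p markers,
# uniform positive intensities, one batch unless n_batches given.
tiny_table <- function(n_case = 4, n_control = 5, p = 3, n_batches = 1,
                       seed = 42) {
  n <- n_case + n_control
  x <- metaboselect:::local_seed(seed,
    matrix(stats::runif(n * p, 1, 100), n, p))
  feature_table(x,
                group = rep(c("case", "control"), c(n_case, n_control)),
                batch = rep_len(paste0("B", seq_len(n_batches)), n))
}

# Exhaustive Mann-Whitney oracle: all case-control pairs, ties count 1/2.
auc_oracle <- function(values, groups) {
  cs <- values[groups == "case"]
  ct <- values[groups == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# Direct VIP formula oracle from stored weights and explained response SS.
vip_oracle <- function(W, ssy, a) {
  p <- nrow(W)
  sapply(seq_len(p), function(j) {
    sqrt(p * sum(ssy[1:a] * W[j, 1:a]^2) / sum(ssy[1:a]))
  })
}

# Independent NIPALS hand-iteration for a centered X and centered 0/1 y:
# plain loops, no shared code with fit_plsda.
nipals_oracle <- function(X, y, A) {
  X <- sweep(X, 2, colMeans(X))
  y <- y - mean(y)
  p <- ncol(X)
  W <- matrix(0, p, A); ssy <- numeric(A)
  for (k in seq_len(A)) {
    u <- y
    w <- numeric(p)
    for (it in 1:500) {
      for (j in seq_len(p)) w[j] <- sum(X[, j] * u)
      w <- w / sqrt(sum(w^2))
      tt <- as.numeric(X %*% w)
      if (it > 1 && sqrt(sum((tt - t_prev)^2)) < 1e-10 * sqrt(sum(tt^2)))
        break
      t_prev <- tt
    }
    tt <- as.numeric(X %*% w)
    cq <- sum(y * tt) / sum(tt^2)
    pk <- as.numeric(t(X) %*% tt) / sum(tt^2)
    W[, k] <- w
    ssy[k] <- cq^2 * sum(tt^2)
    X <- X - outer(tt, pk)
    y <- y - cq * tt
  }
  list(W = W, ssy = ssy)
}
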
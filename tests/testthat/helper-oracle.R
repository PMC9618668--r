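# Independent oracles, deliberately implemented without reusing package
# internals.

# all nonnegative integer k-vectors summing to n
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  do.call(rbind, lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1L))))
}

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Brute-force posterior mean of theta for the single-stock (M = 1) model:
# latent source allocations are enumerated exactly (the baseline
# frequencies integrate analytically as Dirichlet-multinomials), and the
# remaining R-dimensional integral over the dispersal rows phi_r =
# (x_r, 1 - x_r) is done by midpoint quadrature on a K^R grid.
oracle_theta_mean <- function(X, y, N, alpha, beta, K = 96L) {
  R <- nrow(X); H <- ncol(X)
  stopifnot(length(y) == H, ncol(alpha) == 2L)
  states <- list()
  states[[paste(rep(0L, R), collapse = ",")]] <- list(n = rep(0L, R), lw = 0)
  for (h in seq_len(H)) {
    if (y[h] == 0L) next
    comps <- compositions(y[h], R)
    u <- apply(comps, 1L, function(a)
      sum(lgamma(beta + X[, h] + a) - lgamma(beta + X[, h])) +
        lgamma(y[h] + 1) - sum(lgamma(a + 1)))
    nxt <- list()
    for (st in states) {
      for (i in seq_len(nrow(comps))) {
        n2 <- st$n + comps[i, ]
        key <- paste(n2, collapse = ",")
        lw2 <- st$lw + u[i]
        if (is.null(nxt[[key]])) nxt[[key]] <- list(n = n2, lw = lw2)
        else nxt[[key]]$lw <- lse(c(nxt[[key]]$lw, lw2))
      }
    }
    states <- nxt
  }
  Xtot <- rowSums(X)
  cvecs <- t(vapply(states, `[[`, integer(R), "n"))
  lW <- vapply(states, `[[`, 0, "lw") -
    apply(cvecs, 1L, function(n) sum(lgamma(beta * H + Xtot + n)))
  xs <- (seq_len(K) - 0.5) / K
  grid <- as.matrix(do.call(expand.grid, rep(list(xs), R)))
  lprior <- rowSums(vapply(seq_len(R), function(r)
    dbeta(grid[, r], alpha[r, 1L], alpha[r, 2L], log = TRUE),
    numeric(nrow(grid))))
  w <- sweep(grid, 2L, N, "*")
  ltheta <- log(w / rowSums(w))
  lE0 <- ltheta %*% t(cvecs) + lprior      # grid x states
  l0 <- apply(lE0, 2L, lse)
  logZ <- lse(lW + l0)
  vapply(seq_len(R), function(j) {
    l1 <- apply(lE0 + ltheta[, j], 2L, lse)
    exp(lse(lW + l1) - logZ)
  }, numeric(1))
}

# Independent re-implementation of the unnormalized log posterior density,
# assembled from scratch (scalar loops, explicit Dirichlet normalizers).
oracle_log_posterior <- function(X, Y, N, alpha, beta, phi, f) {
  R <- nrow(X); H <- ncol(X); M <- nrow(Y)
  ldir <- function(x, a)
    lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
  lp <- 0
  for (r in seq_len(R)) {
    lp <- lp + ldir(phi[r, ], alpha[r, ]) + ldir(f[r, ], rep(beta, H))
    for (h in seq_len(H)) lp <- lp + X[r, h] * log(f[r, h])
  }
  for (m in seq_len(M)) {
    den <- 0
    for (r in seq_len(R)) den <- den + N[r] * phi[r, m]
    for (h in seq_len(H)) {
      if (Y[m, h] == 0) next
      mix <- 0
      for (r in seq_len(R))
        mix <- mix + (N[r] * phi[r, m] / den) * f[r, h]
      lp <- lp + Y[m, h] * log(mix)
    }
  }
  lp
}
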
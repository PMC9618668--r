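make_spec <- function(X, Y, N, ...) {
  build_model(baseline_table(X, N), mixed_table(Y), ...)
}

test_that("build_model constructs the documented priors", {
  X <- matrix(c(4L, 1L, 2L, 3L), 2, 2,
              dimnames = list(c("A", "B"), c("h1", "h2")))
  Y <- matrix(c(1L, 1L, 2L, 0L), 2, 2,
              dimnames = list(c("S1", "S2"), c("h1", "h2")))
  # variant 1, M = 2, c = 1: uniform rows (1/3, 1/3, 1/3)
  s1 <- make_spec(X, Y, N = c(10, 20), variant = 1)
  expect_equal(unname(s1$alpha), matrix(1 / 3, 2, 3))
  expect_equal(s1$beta, 1 / 2)

  # transport scaling with residual-to-unknown: p = (0.2, 0.3) -> (0.2, 0.3, 0.5)
  p <- matrix(c(0.2, 0.1, 0.3, 0.2), 2, 2,
              dimnames = list(NULL, c("S1", "S2")))
  b <- baseline_table(X, N = c(10, 20), p = p)
  s2 <- build_model(b, mixed_table(Y), variant = 2)
  expect_equal(unname(s2$alpha[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(unname(s2$alpha[2, ]), c(0.1, 0.2, 0.7))

  expect_error(make_spec(X, Y, N = c(10, 20), variant = 2), "transport")
  expect_error(make_spec(X, Y, N = c(10, 20), variant = 5), "variant")
})

test_that("zero-transport rookeries are excluded from transport variants", {
  X <- matrix(c(4L, 1L, 2L, 3L, 1L, 1L), 3, 2,
              dimnames = list(c("A", "B", "SOFL"), c("h1", "h2")))
  Y <- matrix(c(1L, 1L), 1, 2, dimnames = list("S1", c("h1", "h2")))
  p <- matrix(c(0.2, 0.1, 0), 3, 1, dimnames = list(NULL, "S1"))
  b <- baseline_table(X, N = c(10, 20, 30), p = p)
  s <- build_model(b, mixed_table(Y), variant = 2)
  expect_equal(s$excluded, "SOFL")
  expect_equal(s$rookery_codes, c("A", "B"))
  expect_equal(s$R, 2L)
  # same data under variant 1 keeps all rookeries
  expect_equal(build_model(b, mixed_table(Y), variant = 1)$R, 3L)
})

test_that("theta transform weights dispersal by rookery size", {
  # R = 1: sole source gets everything
  expect_equal(unname(theta_from_phi(matrix(c(0.3, 0.7), 1, 2), N = 5)),
               matrix(1, 1, 1))
  # equal N and phi: uniform over rookeries
  phi <- matrix(1 / 3, 4, 3)
  expect_equal(unname(theta_from_phi(phi, N = rep(7, 4))),
               matrix(1 / 4, 2, 4))
  # hand case: N = (100, 300), phi_col = (0.2, 0.1) -> (0.4, 0.6)
  phi2 <- cbind(c(0.2, 0.1), 1 - c(0.2, 0.1))
  expect_equal(unname(theta_from_phi(phi2, N = c(100, 300))[1, ]),
               c(0.4, 0.6))
  expect_error(theta_from_phi(phi2, N = c(1, 2, 3)), "length")
})

test_that("log posterior matches an independent re-implementation", {
  set.seed(31)
  X <- matrix(c(4L, 1L, 2L, 6L), 2, 2,
              dimnames = list(c("A", "B"), c("h1", "h2")))
  Y <- matrix(c(3L, 2L), 1, 2, dimnames = list("S", c("h1", "h2")))
  spec <- make_spec(X, Y, N = c(50, 10), variant = 1)
  rdir <- function(a) { g <- rgamma(length(a), a); g / sum(g) }
  for (i in 1:20) {
    phi <- t(replicate(2, rdir(c(2, 2))))
    f <- t(replicate(2, rdir(c(2, 2))))
    expect_equal(log_posterior(spec, phi, f),
                 oracle_log_posterior(spec$X, spec$Y, spec$N, spec$alpha,
                                      spec$beta, phi, f),
                 tolerance = 1e-10)
  }
})

test_that("log posterior degenerates correctly", {
  X <- matrix(c(4L, 1L, 2L, 6L), 2, 2,
              dimnames = list(c("A", "B"), c("h1", "h2")))
  Y <- matrix(c(3L, 2L), 1, 2, dimnames = list("S", c("h1", "h2")))
  spec <- make_spec(X, Y, N = c(50, 10), variant = 1)
  phi <- matrix(0.5, 2, 2)
  f <- matrix(c(0.3, 0.6, 0.7, 0.4), 2, 2)

  # with Y zeroed the density reduces to prior + baseline terms
  spec0 <- spec; spec0$Y <- matrix(0L, 1, 2)
  prior_base <- sum(vapply(1:2, function(r)
    manymix:::.log_ddirichlet(phi[r, ], spec$alpha[r, ]) +
      manymix:::.log_ddirichlet(f[r, ], rep(spec$beta, 2)), 0)) +
    sum(spec$X * log(f))
  expect_equal(log_posterior(spec0, phi, f), prior_base)

  # single rookery: mixture term is the multinomial log-likelihood under f
  spec1 <- make_spec(X[1, , drop = FALSE], Y, N = 50, variant = 1)
  phi1 <- matrix(c(0.4, 0.6), 1, 2)
  f1 <- matrix(c(0.3, 0.7), 1, 2)
  expect_equal(log_posterior(spec1, phi1, f1),
               manymix:::.log_ddirichlet(phi1[1, ], spec1$alpha[1, ]) +
                 manymix:::.log_ddirichlet(f1[1, ], rep(spec1$beta, 2)) +
                 sum(spec1$X * log(f1)) + sum(Y * log(f1)))

  # observed haplotype with zero mixture probability: -Inf, no exception
  fz <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_identical(log_posterior(spec, phi, fz), -Inf)
})

test_that("single-rookery chains put all contribution mass on that rookery", {
  X <- matrix(c(3L, 7L), 1, 2, dimnames = list("A", c("h1", "h2")))
  Y <- matrix(c(2L, 2L), 1, 2, dimnames = list("S", c("h1", "h2")))
  d <- run_chain(make_spec(X, Y, N = 1), iterations = 300, burn_in = 50,
                 seed = 5)
  expect_true(all(d$theta == 1))
  m1 <- fit_many_to_one(baseline_table(X, N = 1), mixed_table(Y),
                        iterations = 300, burn_in = 50, seed = 5)
  expect_true(all(m1$theta == 1))
})

test_that("chains are bit-for-bit reproducible and draws stay on simplices", {
  set.seed(32)
  tt <- random_tables(R = 3, M = 2, H = 4)
  spec <- build_model(tt$baseline, tt$mixed, variant = 1)
  d1 <- run_chain(spec, iterations = 2000, burn_in = 500, seed = 99,
                  store_f = TRUE)
  d2 <- run_chain(spec, iterations = 2000, burn_in = 500, seed = 99,
                  store_f = TRUE)
  expect_identical(d1$phi, d2$phi)
  expect_identical(d1$theta, d2$theta)
  expect_true(max(abs(apply(d1$phi, c(1, 2), sum) - 1)) < 1e-9)
  expect_true(max(abs(apply(d1$theta, c(1, 2), sum) - 1)) < 1e-9)
  expect_true(max(abs(apply(d1$f, c(1, 2), sum) - 1)) < 1e-9)
  expect_true(all(d1$phi >= 0 & d1$phi <= 1))

  ft1 <- fit(spec, chains = 2, iterations = 1500, burn_in = 500, seed = 7)
  ft2 <- fit(spec, chains = 2, iterations = 1500, burn_in = 500, seed = 7)
  expect_identical(ft1$summary, ft2$summary)
})

test_that("orphan haplotypes and bad run lengths are rejected", {
  X <- matrix(c(5L, 0L), 1, 2, dimnames = list("A", c("h1", "h2")))
  Y <- matrix(c(1L, 2L), 1, 2, dimnames = list("S", c("h1", "h2")))
  spec <- make_spec(X, Y, N = 1)
  expect_error(run_chain(spec, iterations = 100, burn_in = 10, seed = 1),
               "orphan.*h2")
  Xok <- matrix(c(5L, 1L), 1, 2, dimnames = list("A", c("h1", "h2")))
  expect_error(run_chain(make_spec(Xok, Y, N = 1), iterations = 100,
                         burn_in = 100, seed = 1),
               "iterations > burn_in")
})

test_that("rookery relabeling permutes deterministic outputs exactly", {
  set.seed(33)
  tt <- random_tables(R = 4, M = 2, H = 5)
  perm <- c(3, 1, 4, 2)
  bp <- baseline_table(tt$baseline$X[perm, ], tt$baseline$N[perm])
  s0 <- build_model(tt$baseline, tt$mixed, variant = 1)
  sp <- build_model(bp, tt$mixed, variant = 1)
  expect_equal(unname(sp$alpha), unname(s0$alpha[perm, ]))
  phi <- t(replicate(4, { g <- rgamma(3, 1); g / sum(g) }))
  f <- t(replicate(4, { g <- rgamma(5, 1); g / sum(g) }))
  expect_equal(unname(theta_from_phi(phi[perm, ], tt$baseline$N[perm])),
               unname(theta_from_phi(phi, tt$baseline$N)[, perm]))
  expect_equal(log_posterior(sp, phi[perm, ], f[perm, ]),
               log_posterior(s0, phi, f))
})

test_that("permuting rookeries leaves posterior means unchanged in distribution", {
  set.seed(34)
  tt <- random_tables(R = 3, M = 1, H = 3)
  perm <- c(2, 3, 1)
  bp <- baseline_table(tt$baseline$X[perm, ], tt$baseline$N[perm])
  f0 <- fit(build_model(tt$baseline, tt$mixed), chains = 2,
            iterations = 15000, burn_in = 3000, seed = 11)
  fp <- fit(build_model(bp, tt$mixed), chains = 2,
            iterations = 15000, burn_in = 3000, seed = 12)
  m0 <- f0$summary$theta$mean[match(bp$rookery_codes,
                                    f0$summary$theta$rookery)]
  expect_lt(max(abs(fp$summary$theta$mean - m0)), 0.02)
})

test_that("posterior mass per stock is conserved and priors dominate tiny samples", {
  set.seed(35)
  tt <- random_tables(R = 3, M = 2, H = 4)
  spec <- build_model(tt$baseline, tt$mixed, variant = 1)
  ft <- fit(spec, chains = 2, iterations = 4000, burn_in = 1000, seed = 2)
  sums <- tapply(ft$summary$theta$mean, ft$summary$theta$stock, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-6)

  # with no mixed individuals at all, theta matches its prior mean
  spec0 <- spec
  spec0$Y <- matrix(0L, spec$M, spec$H)
  d <- run_chain(spec0, iterations = 30000, burn_in = 2000, seed = 3)
  post_mean <- apply(d$theta, c(2, 3), mean)
  set.seed(4)
  prior_draws <- replicate(30000, {
    phi <- t(apply(spec$alpha, 1, function(a) {
      g <- rgamma(length(a), a); g[g < 1e-300] <- 1e-300; g / sum(g)
    }))
    theta_from_phi(phi, spec$N)
  })
  prior_mean <- apply(prior_draws, c(1, 2), mean)
  expect_lt(max(abs(post_mean - unname(prior_mean))), 0.02)
})

test_that("many-to-many and many-to-one agree in the single-stock limit", {
  set.seed(36)
  X <- matrix(c(12L, 2L, 1L, 1L, 3L, 11L), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("h1", "h2", "h3")))
  Y <- matrix(c(6L, 4L, 5L), 1, 3, dimnames = list("S", c("h1", "h2", "h3")))
  b <- baseline_table(X, N = c(1, 1))  # equal sizes
  m <- mixed_table(Y)
  mm <- fit(build_model(b, m, variant = 1), chains = 2,
            iterations = 30000, burn_in = 5000, seed = 21)
  # matched flat prior: the induced theta prior mean is uniform for equal N
  mo <- fit_many_to_one(b, m, prior = c(0.5, 0.5), chains = 2,
                        iterations = 30000, burn_in = 5000, seed = 22)
  expect_lt(max(abs(mm$summary$theta$mean - mo$summary$mean)), 0.02)
})

test_that("freezing baseline frequencies is honoured as a sensitivity switch", {
  set.seed(37)
  tt <- random_tables(R = 2, M = 1, H = 3)
  spec <- build_model(tt$baseline, tt$mixed, variant = 1)
  d_free <- run_chain(spec, iterations = 3000, burn_in = 500, seed = 8)
  d_frozen <- run_chain(spec, iterations = 3000, burn_in = 500, seed = 8,
                        update_f = FALSE)
  expect_false(identical(d_free$theta, d_frozen$theta))
  expect_true(max(abs(apply(d_frozen$theta, c(1, 2), sum) - 1)) < 1e-9)
})
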
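.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g[g < 1e-300] <- 1e-300
  g / sum(g)
}

# prior draw nudged off the machine-zero boundary; used for chain starts
.rdirichlet_init <- function(alpha, floor = 1e-8) {
  x <- pmax(.rdirichlet1(alpha), floor)
  x / sum(x)
}

.check_orphans <- function(spec) {
  orph <- colSums(spec$Y) > 0 & colSums(spec$X) == 0
  if (any(orph))
    stop("orphan haplotype(s) reached the sampler (present in a mixed ",
         "stock, absent from every baseline): ",
         paste(spec$haplotype_names[orph], collapse = ", "))
}

# derive M x R theta draws from an n x R x (M+1) phi array
.theta_draws <- function(phi_arr, N) {
  n <- dim(phi_arr)[1L]; R <- dim(phi_arr)[2L]; M <- dim(phi_arr)[3L] - 1L
  theta <- array(NA_real_, dim = c(n, M, R))
  for (m in seq_len(M)) {
    wm <- matrix(phi_arr[, , m], nrow = n, ncol = R)
    wm <- sweep(wm, 2L, N, "*")
    dm <- rowSums(wm)
    bad <- dm == 0
    if (any(bad)) {
      wm[bad, ] <- matrix(N / sum(N), sum(bad), R, byrow = TRUE)
      dm[bad] <- 1
    }
    theta[, m, ] <- wm / dm
  }
  theta
}

#' Run one MCMC chain of the many-to-many model
#'
#' Data-augmented sampler targeting the posterior defined by
#' [log_posterior()]: latent source labels are Gibbs-sampled per mixed
#' individual, baseline frequencies are conjugate-Dirichlet updated, and
#' each rookery's dispersal row \eqn{\phi_r} is updated by
#' Metropolis-within-Gibbs with an adaptive Dirichlet proposal (adaptation
#' during burn-in only).  Identical `(seed, inputs)` reproduce the chain
#' bit for bit.
#'
#' @param spec a [build_model()] specification.
#' @param iterations total iterations (default 100000, the study setting).
#' @param burn_in discarded initial iterations (default 50000).
#' @param seed integer seed for this chain.
#' @param init optional list with elements `phi` and `f`; when `NULL`,
#'   `phi` rows are drawn from their Dirichlet priors (overdispersed
#'   starts) and `f` rows from their baseline-only conditionals.
#' @param update_f if `FALSE`, mixed-stock individuals do not feed back
#'   into the baseline frequencies: `f` is drawn from its baseline-only
#'   posterior throughout (sensitivity switch).
#' @param store_f retain the `f` draws (off by default; memory).
#' @param kappa0 initial Dirichlet proposal concentration.
#' @param max_init_retries re-draws allowed when the initial point has
#'   non-finite posterior density.
#' @return An object of class `posterior_draws`: list with `phi`
#'   (draws x R x (M+1) array), `theta` (draws x M x R), optionally `f`,
#'   plus `chain_id`, `iterations`, `burn_in`, `seed`, `accept`
#'   (per-rookery Metropolis acceptance rates) and axis names.
#' @export
run_chain <- function(spec, iterations = 100000L, burn_in = 50000L,
                      seed = 1L, init = NULL, update_f = TRUE,
                      store_f = FALSE, kappa0 = 200,
                      max_init_retries = 20L) {
  stopifnot(inherits(spec, "model_spec"))
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (!(iterations > burn_in && burn_in >= 0L))
    stop("need iterations > burn_in >= 0")
  .check_orphans(spec)
  set.seed(seed)
  if (is.null(init)) {
    ok <- FALSE
    for (try in seq_len(max_init_retries)) {
      phi0 <- t(apply(spec$alpha, 1L, .rdirichlet_init))
      f0 <- t(apply(spec$X, 1L,
                    function(x) .rdirichlet_init(spec$beta + x, 1e-10)))
      if (is.finite(log_posterior(spec, phi0, f0))) { ok <- TRUE; break }
    }
    if (!ok) stop("could not find an initial point with finite posterior ",
                  "density after ", max_init_retries, " attempts")
  } else {
    phi0 <- as.matrix(init$phi); f0 <- as.matrix(init$f)
    if (!is.finite(log_posterior(spec, phi0, f0)))
      stop("supplied init has non-finite posterior density")
  }
  res <- .mm_chain_cpp(spec$X, spec$Y, spec$N, spec$alpha, spec$beta,
                       iterations, burn_in, phi0, f0, kappa0, update_f,
                       store_f)
  n_keep <- iterations - burn_in
  phi_arr <- array(res$phi, dim = c(n_keep, spec$R, spec$M + 1L))
  out <- list(phi = phi_arr,
              theta = .theta_draws(phi_arr, spec$N),
              f = if (store_f) array(res$f, dim = c(n_keep, spec$R, spec$H)),
              chain_id = 1L, iterations = iterations, burn_in = burn_in,
              seed = seed, accept = res$accept, kappa = res$kappa,
              rookery_codes = spec$rookery_codes,
              stock_codes = spec$stock_codes,
              destinations = c(spec$stock_codes, "unknown"))
  class(out) <- "posterior_draws"
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d retained draws (chain %d, seed %d)\n",
              dim(x$phi)[1L], x$chain_id, x$seed))
  cat(sprintf("  %d rookeries -> %d stocks + unknown; mean MH acceptance %.2f\n",
              dim(x$phi)[2L], dim(x$theta)[2L], mean(x$accept)))
  invisible(x)
}

#' Fit the many-to-many mixed stock model
#'
#' Runs several chains from overdispersed starts (independent Dirichlet
#' prior draws; per-chain seeds derived deterministically from the master
#' seed), pools post-burn-in draws, computes Gelman-Rubin shrink factors
#' for every contribution parameter (\eqn{\theta} and \eqn{\phi}), and
#' summarizes posterior means with equal-tailed 95% credibility intervals.
#'
#' @inheritParams run_chain
#' @param chains number of chains, at least 2 (default 4).
#' @param ... further arguments passed to [run_chain()].
#' @return An object of class `mm_fit`: list with `chains` (list of
#'   [run_chain()] results), pooled arrays `theta` and `phi`, `summary`
#'   (list of `theta`/`phi` data frames with mean, lower, upper),
#'   `convergence` (per-parameter shrink factor table), `converged` flag
#'   (`TRUE` when every shrink factor is below 1.2), `seeds`, and `spec`.
#' @export
fit <- function(spec, chains = 4L, iterations = 100000L,
                burn_in = 50000L, seed = 1L, ...) {
  stopifnot(inherits(spec, "model_spec"))
  chains <- as.integer(chains)
  if (chains < 2L) stop("need at least 2 chains for convergence diagnostics")
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  runs <- vector("list", chains)
  for (k in seq_len(chains)) {
    runs[[k]] <- run_chain(spec, iterations = iterations, burn_in = burn_in,
                           seed = chain_seeds[k], ...)
    runs[[k]]$chain_id <- k
  }
  theta_pooled <- do.call(.abind1, lapply(runs, `[[`, "theta"))
  phi_pooled <- do.call(.abind1, lapply(runs, `[[`, "phi"))
  conv <- convergence_report(runs)
  summ <- list(
    theta = .summarize_param(theta_pooled, runs[[1L]]$stock_codes,
                             runs[[1L]]$rookery_codes,
                             c("stock", "rookery")),
    phi = .summarize_param(phi_pooled, runs[[1L]]$rookery_codes,
                           runs[[1L]]$destinations,
                           c("rookery", "destination")))
  out <- list(chains = runs, theta = theta_pooled, phi = phi_pooled,
              summary = summ, convergence = conv,
              converged = all(conv$Rhat < 1.2, na.rm = TRUE),
              seeds = chain_seeds, master_seed = seed, spec = spec)
  class(out) <- "mm_fit"
  out
}

# bind draw arrays along the first (draw) dimension
.abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- vapply(arrs, function(a) dim(a)[1L], 0L)
  out <- array(NA_real_, dim = c(sum(n), d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("mm_fit: variant %d, %d chains x %d retained draws\n",
              x$spec$variant, length(x$chains), dim(x$chains[[1L]]$theta)[1L]))
  cat(sprintf("  max shrink factor %.3f (%s)\n", max(x$convergence$Rhat),
              if (x$converged) "converged, < 1.2" else ">= 1.2: NOT converged"))
  for (m in seq_along(x$spec$stock_codes)) {
    s <- x$summary$theta[x$summary$theta$stock == x$spec$stock_codes[m], ]
    top <- s[order(-s$mean)[1:min(3L, nrow(s))], ]
    cat(sprintf("  %s top contributions: %s\n", x$spec$stock_codes[m],
                paste(sprintf("%s %.2f [%.2f-%.2f]", top$rookery, top$mean,
                              top$lower, top$upper), collapse = ", ")))
  }
  invisible(x)
}

#' Fit the classic many-to-one mixed stock model
#'
#' Standard Dirichlet-multinomial mixture for a single mixed stock: fully
#' conjugate Gibbs on latent sources `z`, contributions `theta` (Dirichlet
#' prior `prior`) and baseline frequencies `f`.  Provided both as the
#' reference model the many-to-many approach generalizes and as a
#' cross-check in the single-stock limit.
#'
#' @param baseline a [baseline_table()].
#' @param mixed a [mixed_table()] with exactly one stock, sharing the
#'   baseline haplotype axis.
#' @param prior Dirichlet prior vector on `theta` (length R); default
#'   `1/R` per rookery.
#' @param beta per-haplotype Dirichlet mass for baseline frequencies
#'   (default `1/H`).
#' @param chains,iterations,burn_in,seed as in [fit()].
#' @param update_f as in [run_chain()].
#' @return A list of class `m1_fit` with pooled `theta` draws
#'   (draws x R), `summary` data frame, `convergence` table and
#'   `converged` flag.
#' @export
fit_many_to_one <- function(baseline, mixed, prior = NULL, beta = NULL,
                            chains = 2L, iterations = 20000L,
                            burn_in = 5000L, seed = 1L, update_f = TRUE) {
  stopifnot(inherits(baseline, "baseline_table"),
            inherits(mixed, "mixed_table"))
  if (nrow(mixed$Y) != 1L)
    stop("fit_many_to_one needs exactly one mixed stock")
  if (!identical(baseline$haplotype_names, mixed$haplotype_names))
    stop("tables are not harmonized: haplotype axes differ")
  orph <- colSums(mixed$Y) > 0 & colSums(baseline$X) == 0
  if (any(orph))
    stop("orphan haplotype(s): ",
         paste(baseline$haplotype_names[orph], collapse = ", "))
  R <- nrow(baseline$X); H <- ncol(baseline$X)
  if (is.null(prior)) prior <- rep(1 / R, R)
  if (length(prior) != R || any(prior <= 0))
    stop("prior must be a positive vector of length R")
  if (is.null(beta)) beta <- 1 / H
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (!(iterations > burn_in && burn_in >= 0L))
    stop("need iterations > burn_in >= 0")
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  draws <- vector("list", chains)
  for (k in seq_len(chains)) {
    set.seed(chain_seeds[k])
    theta0 <- .rdirichlet1(prior)
    f0 <- t(apply(baseline$X, 1L, function(x) .rdirichlet1(beta + x)))
    res <- .m1_chain_cpp(unname(baseline$X), unname(mixed$Y[1L, ]), prior,
                         beta, iterations, burn_in, theta0, f0, update_f)
    colnames(res$theta) <- baseline$rookery_codes
    draws[[k]] <- res$theta
  }
  pooled <- do.call(rbind, draws)
  conv <- do.call(rbind, lapply(seq_len(R), function(r) {
    e <- shrink_factor(t(vapply(draws, function(d) d[, r],
                                numeric(nrow(draws[[1L]])))))
    data.frame(parameter = sprintf("theta[%s]", baseline$rookery_codes[r]),
               W = e$W, B = e$B, Vhat = e$Vhat, Rhat = e$Rhat)
  }))
  qs <- apply(pooled, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  summ <- data.frame(stock = mixed$stock_codes,
                     rookery = baseline$rookery_codes,
                     mean = colMeans(pooled),
                     lower = qs[1L, ], upper = qs[2L, ],
                     row.names = NULL)
  structure(list(theta = pooled, summary = summ, convergence = conv,
                 converged = all(conv$Rhat < 1.2, na.rm = TRUE),
                 seeds = chain_seeds),
            class = "m1_fit")
}
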
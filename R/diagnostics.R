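#' Gelman-Rubin shrink factor for one scalar parameter
#'
#' Classic potential scale reduction factor (no rank normalization, no
#' degrees-of-freedom correction), the diagnostic conventionally compared
#' against a 1.2 threshold: with C chains of n retained draws each,
#' \eqn{W} is the mean of the unbiased within-chain variances, \eqn{B}
#' is \eqn{n} times the unbiased variance of the chain means,
#' \eqn{\hat V = \frac{n-1}{n} W + \frac{B}{n}} and
#' \eqn{\hat R = \sqrt{\hat V / W}}.  Chains that are constant everywhere
#' (and equal) return \eqn{\hat R = 1} by convention.
#'
#' @param chains a C x n numeric matrix (one row per chain) or a list of
#'   equal-length numeric vectors.
#' @return A list with `W`, `B`, `Vhat`, `Rhat`, `n`, `C` and the logical
#'   `converged` (`Rhat < 1.2`).
#' @export
shrink_factor <- function(chains) {
  if (is.list(chains)) chains <- do.call(rbind, chains)
  chains <- as.matrix(chains)
  C <- nrow(chains); n <- ncol(chains)
  if (C < 2L) stop("shrink factor needs at least 2 chains")
  if (n < 2L) stop("shrink factor needs at least 2 draws per chain")
  W <- mean(apply(chains, 1L, var))
  B <- n * var(rowMeans(chains))
  if (W == 0) {
    # constant chains: R = 1 by convention when the chains agree, else Inf
    Rhat <- if (B == 0) 1 else Inf
    Vhat <- B / n
  } else {
    Vhat <- (n - 1) / n * W + B / n
    Rhat <- sqrt(Vhat / W)
  }
  list(W = W, B = B, Vhat = Vhat, Rhat = Rhat, n = n, C = C,
       converged = Rhat < 1.2)
}

#' Per-parameter convergence report
#'
#' Computes the shrink factor of every scalar contribution parameter:
#' each \eqn{\theta_{m,r}} (mixture-centric) and each \eqn{\phi_{r,d}}
#' (rookery-centric, including the unknown sink).
#'
#' @param chains a list of [run_chain()] results (equal lengths), or an
#'   `mm_fit` object.
#' @return A data frame of class `convergence_report` with columns
#'   `parameter`, `W`, `B`, `Vhat`, `Rhat`, `converged`.
#' @export
convergence_report <- function(chains) {
  if (inherits(chains, "mm_fit")) chains <- chains$chains
  stopifnot(is.list(chains), length(chains) >= 2L)
  ex <- chains[[1L]]
  n <- dim(ex$theta)[1L]
  pull <- function(field, i, j)
    t(vapply(chains, function(ch) ch[[field]][, i, j], numeric(n)))
  rows <- list()
  for (m in seq_along(ex$stock_codes))
    for (r in seq_along(ex$rookery_codes)) {
      e <- shrink_factor(pull("theta", m, r))
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = sprintf("theta[%s,%s]", ex$stock_codes[m],
                                       ex$rookery_codes[r]),
                   W = e$W, B = e$B, Vhat = e$Vhat, Rhat = e$Rhat,
                   converged = e$converged)
    }
  for (r in seq_along(ex$rookery_codes))
    for (d in seq_along(ex$destinations)) {
      e <- shrink_factor(pull("phi", r, d))
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = sprintf("phi[%s,%s]", ex$rookery_codes[r],
                                       ex$destinations[d]),
                   W = e$W, B = e$B, Vhat = e$Vhat, Rhat = e$Rhat,
                   converged = e$converged)
    }
  out <- do.call(rbind, rows)
  class(out) <- c("convergence_report", "data.frame")
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  worst <- which.max(x$Rhat)
  cat(sprintf("convergence_report: %d parameters; worst Rhat %.4f (%s), %s\n",
              nrow(x), x$Rhat[worst], x$parameter[worst],
              if (all(x$converged)) "all < 1.2" else "NOT all < 1.2"))
  NextMethod()
}

# mean + equal-tailed 95% interval (linear-interpolation quantiles) for an
# n x A x B draw array
.summarize_param <- function(arr, a_names, b_names, a_b_labels) {
  if (dim(arr)[1L] < 1L) stop("no draws to summarize")
  rows <- list()
  for (i in seq_along(a_names))
    for (j in seq_along(b_names)) {
      d <- arr[, i, j]
      q <- quantile(d, probs = c(0.025, 0.975), names = FALSE, type = 7)
      rows[[length(rows) + 1L]] <-
        setNames(data.frame(a_names[i], b_names[j], mean(d), q[1L], q[2L],
                            stringsAsFactors = FALSE),
                 c(a_b_labels, "mean", "lower", "upper"))
    }
  do.call(rbind, rows)
}

#' Posterior contribution summary
#'
#' Means and equal-tailed 95% credibility intervals (2.5% and 97.5%
#' linear-interpolation quantiles) per contribution parameter.
#'
#' @param draws a [run_chain()] `posterior_draws` object, an `mm_fit`, or
#'   a plain draws matrix (draws x parameters).
#' @return For draw objects, a list of data frames `theta` (per stock and
#'   rookery) and `phi` (per rookery and destination); for a matrix, one
#'   data frame with a `parameter` column.
#' @export
summarize_draws <- function(draws) {
  if (inherits(draws, "mm_fit"))
    return(draws$summary)
  if (inherits(draws, "posterior_draws")) {
    if (dim(draws$theta)[1L] < 100L)
      warning("fewer than 100 retained draws; summaries will be noisy")
    return(list(
      theta = .summarize_param(draws$theta, draws$stock_codes,
                               draws$rookery_codes, c("stock", "rookery")),
      phi = .summarize_param(draws$phi, draws$rookery_codes,
                             draws$destinations,
                             c("rookery", "destination"))))
  }
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) stop("no draws to summarize")
  if (is.null(colnames(draws)))
    colnames(draws) <- sprintf("par%d", seq_len(ncol(draws)))
  qs <- apply(draws, 2L, quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  data.frame(parameter = colnames(draws), mean = colMeans(draws),
             lower = qs[1L, ], upper = qs[2L, ], row.names = NULL)
}
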
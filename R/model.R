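#' Build a many-to-many mixed stock model specification
#'
#' Encodes one of the four model variants.  All variants parameterize each
#' rookery by a rookery-centric dispersal vector \eqn{\phi_r} over the M
#' sampled mixed stocks plus an "unknown" sink, with a Dirichlet prior of
#' total mass `c_mass` per rookery.  Variants 1 and 3 use a uniform prior;
#' variants 2 and 4 scale the prior by ocean-current transport
#' probabilities, the unknown sink receiving the residual probability
#' \eqn{\max(0, 1 - \sum_m p_{r,m})}, with a small floor `epsilon` applied
#' before renormalization so no hyperparameter is exactly zero.  Variants 2
#' and 4 also exclude rookeries whose transport probability is zero for
#' every sampled stock (their prior would place essentially no individuals
#' in any sampled area).  Variants 3 and 4 differ from 1 and 2 only in that
#' the mixed table is expected to have been augmented with additional
#' published samples before entry; the specification itself is identical.
#'
#' Rookery size enters the model only through the deterministic
#' [theta_from_phi()] transform; transport probability only through the
#' prior on \eqn{\phi}.  This keeps the two covariates separately
#' switchable, realizing the four variants.
#'
#' @param baseline a harmonized [baseline_table()].
#' @param mixed a harmonized [mixed_table()] sharing the haplotype axis.
#' @param variant integer 1-4.
#' @param c_mass total Dirichlet prior mass per rookery row (default 1).
#' @param beta symmetric Dirichlet mass per haplotype for baseline
#'   frequencies; default `1/H`, weakly informative.
#' @param epsilon floor applied to transport-scaled prior entries before
#'   renormalization (default 1e-3).
#' @param use_sizes logical; if `FALSE` rookery sizes are replaced by 1 in
#'   the size transform (all variants of the study use sizes).
#' @return An object of class `model_spec`: list with `R`, `M`, `H`,
#'   `rookery_codes`, `stock_codes`, `haplotype_names`, `alpha`
#'   (R x (M+1) Dirichlet hyperparameters, last column the unknown sink),
#'   `beta`, `N`, `X`, `Y`, `variant`, `use_transport`, `excluded`.
#' @export
build_model <- function(baseline, mixed, variant = 1L, c_mass = 1,
                        beta = NULL, epsilon = 1e-3, use_sizes = TRUE) {
  stopifnot(inherits(baseline, "baseline_table"),
            inherits(mixed, "mixed_table"))
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4")
  if (!identical(baseline$haplotype_names, mixed$haplotype_names))
    stop("tables are not harmonized: haplotype axes differ")
  use_transport <- variant %in% c(2L, 4L)
  if (use_transport && is.null(baseline$p))
    stop("variant ", variant,
         " requires transport probabilities, but baseline$p is absent")
  M <- nrow(mixed$Y)
  excluded <- character(0)
  if (use_transport) {
    if (!identical(colnames(baseline$p), mixed$stock_codes))
      stop("transport probability columns must match the mixed stock codes")
    zero <- rowSums(baseline$p) == 0
    excluded <- baseline$rookery_codes[zero]
    if (all(zero)) stop("all rookeries have zero transport probability")
    if (any(zero))
      baseline <- baseline_table(baseline$X[!zero, , drop = FALSE],
                                 baseline$N[!zero],
                                 baseline$p[!zero, , drop = FALSE])
  }
  R <- nrow(baseline$X)
  H <- ncol(baseline$X)
  if (is.null(beta)) beta <- 1 / H
  if (beta <= 0 || c_mass <= 0) stop("prior masses must be positive")
  if (use_transport) {
    resid <- pmax(0, 1 - rowSums(baseline$p))
    ptil <- cbind(baseline$p, unknown = resid)
    ptil <- pmax(ptil, epsilon)
    ptil <- ptil / rowSums(ptil)
    alpha <- c_mass * ptil
  } else {
    alpha <- matrix(c_mass / (M + 1), R, M + 1)
  }
  dimnames(alpha) <- list(baseline$rookery_codes,
                          c(mixed$stock_codes, "unknown"))
  structure(list(R = R, M = M, H = H,
                 rookery_codes = baseline$rookery_codes,
                 stock_codes = mixed$stock_codes,
                 haplotype_names = baseline$haplotype_names,
                 alpha = alpha, beta = beta,
                 N = if (use_sizes) unname(baseline$N) else rep(1, R),
                 X = unname(baseline$X), Y = unname(mixed$Y),
                 variant = as.integer(variant),
                 use_transport = use_transport,
                 excluded = excluded),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec (variant %d): %d rookeries -> %d stocks + unknown, %d haplotypes\n",
              x$variant, x$R, x$M, x$H))
  if (length(x$excluded))
    cat("  excluded (zero transport):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Mixture-centric contributions from rookery-centric proportions
#'
#' Converts each rookery's distribution over destinations \eqn{\phi} into
#' each destination's composition over sources \eqn{\theta}, weighting by
#' rookery size: \eqn{\theta_{m,r} = N_r \phi_{r,m} / \sum_{r'} N_{r'}
#' \phi_{r',m}}.  Columns for the unknown sink are not returned.  If a
#' stock's denominator is zero (no rookery sends anything there), the
#' N-weighted prior-mean fallback \eqn{\theta_{m,r} \propto N_r} is used
#' and a warning is issued.
#'
#' @param phi numeric R x (M+1) matrix, rows on the simplex.
#' @param N positive rookery sizes, length R.
#' @return M x R matrix of contribution proportions, rows summing to 1.
#' @export
theta_from_phi <- function(phi, N) {
  phi <- as.matrix(phi)
  if (length(N) != nrow(phi)) stop("length(N) must equal nrow(phi)")
  if (any(N <= 0)) stop("rookery sizes must be positive")
  M <- ncol(phi) - 1L
  if (M < 1L) stop("phi needs at least one sampled destination column")
  w <- N * phi[, seq_len(M), drop = FALSE]       # R x M
  denom <- colSums(w)
  theta <- t(w) / denom                           # M x R
  if (any(denom == 0)) {
    warning("zero denominator in theta transform; using N-weighted fallback")
    theta[denom == 0, ] <- N / sum(N)
  }
  dimnames(theta) <- list(colnames(phi)[seq_len(M)], rownames(phi))
  theta
}

.log_ddirichlet <- function(x, alpha) {
  # log density, safe at boundary: zero x with alpha > 1 -> -Inf;
  # zero x with alpha < 1 -> +Inf is suppressed to -Inf only when alpha > 1.
  if (any(x < 0) || abs(sum(x) - 1) > 1e-6) return(-Inf)
  terms <- (alpha - 1) * log(x)
  terms[alpha == 1] <- 0                # 0 * log(0) at flat components
  sum(terms) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Unnormalized log posterior of the many-to-many model
#'
#' \deqn{\log p \propto \sum_r \log \mathrm{Dir}(\phi_r; \alpha_r)
#'   + \sum_r \log \mathrm{Dir}(f_r; \beta)
#'   + \sum_{r,h} X_{rh} \log f_{rh}
#'   + \sum_{m,h} Y_{mh} \log \sum_r \theta_{mr} f_{rh}}
#' with \eqn{\theta} from [theta_from_phi()].  Finite for strictly interior
#' points; a boundary point that zeroes the probability of an observed
#' haplotype returns `-Inf` rather than raising an error.
#'
#' @param spec a [build_model()] specification.
#' @param phi R x (M+1) matrix on row simplices.
#' @param f R x H matrix on row simplices.
#' @return scalar log density (unnormalized).
#' @export
log_posterior <- function(spec, phi, f) {
  stopifnot(inherits(spec, "model_spec"))
  phi <- as.matrix(phi); f <- as.matrix(f)
  if (!all(dim(phi) == c(spec$R, spec$M + 1L)) ||
      !all(dim(f) == c(spec$R, spec$H)))
    stop("phi or f has the wrong shape for this model_spec")
  lp <- 0
  for (r in seq_len(spec$R))
    lp <- lp + .log_ddirichlet(phi[r, ], spec$alpha[r, ]) +
      .log_ddirichlet(f[r, ], rep(spec$beta, spec$H))
  if (!is.finite(lp)) return(-Inf)
  # baseline multinomial terms
  lf <- suppressWarnings(log(f))
  bl <- spec$X * lf
  bl[spec$X == 0] <- 0
  lp <- lp + sum(bl)
  # mixture terms
  theta <- suppressWarnings(theta_from_phi(phi, spec$N))
  mix <- theta %*% f                      # M x H
  lm_ <- suppressWarnings(log(mix))
  mt <- spec$Y * lm_
  mt[spec$Y == 0] <- 0
  lp <- lp + sum(mt)
  if (is.nan(lp)) -Inf else lp
}
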
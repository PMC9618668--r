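#' Read and validate a pipeline run configuration
#'
#' The configuration is a single YAML file (one source of truth per run).
#' Recognized fields, with defaults matching the study settings where the
#' study states them: `baseline` (path, required), `mixed` (path,
#' required), `mixed_augmented` (path, optional; used for variants 3 and 4
#' in place of `mixed`), `fasta` (optional haplotype reference FASTA; when
#' given, haplotypes are collapsed to short-fragment classes before
#' harmonization), `window` (truncation window, default `[0, 490]`),
#' `variants` (default `[1]`), `iterations` (default 100000), `burn_in`
#' (default 50000), `chains` (default 4), `seed` (default 1), `orphans`
#' (`error`/`drop`, default `error`), `outdir` (required),
#' `write_draws` (default `TRUE`), `max_draw_rows` (thinning cap for the
#' draws file, default 4000).
#'
#' @param path path to a YAML file, or a named list with the same fields.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(variants = 1L, iterations = 100000L, burn_in = 50000L,
                   chains = 4L, seed = 1L, orphans = "error",
                   window = c(0L, 490L), write_draws = TRUE,
                   max_draw_rows = 4000L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("baseline", "mixed", "outdir"))
    if (is.null(cfg[[nm]])) stop("run config is missing required field: ", nm)
  for (nm in c("baseline", "mixed", "mixed_augmented", "fasta"))
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("run config references a missing file: ", cfg[[nm]])
  cfg$variants <- as.integer(unlist(cfg$variants))
  if (!all(cfg$variants %in% 1:4)) stop("variants must be within 1..4")
  if (!(cfg$iterations > cfg$burn_in && cfg$burn_in >= 0))
    stop("need iterations > burn_in >= 0")
  if (!cfg$orphans %in% c("error", "drop"))
    stop("orphans must be 'error' or 'drop'")
  structure(cfg, class = "run_config")
}

.log_line <- function(logfile, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(line)
  cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full mixed stock analysis pipeline
#'
#' Orchestrates harmonize -> build model variants -> fit -> diagnose ->
#' report from a configuration (see [read_run_config()]).  Each requested
#' variant gets a subdirectory of `outdir` containing `summary.csv`
#' (posterior means and 95% credibility intervals for theta and phi),
#' `convergence.csv`, `draws.csv` (post-burn-in draws in long columnar
#' form, thinned to at most `max_draw_rows` draws) and `manifest.json`
#' (inputs, dimensions, seeds, exclusions, options).  A top-level
#' `pipeline.log` records rookery exclusions and orphan decisions.
#'
#' @param config a [read_run_config()] result, a path to a YAML config, or
#'   a config list.
#' @return Invisibly, a named list of `mm_fit` objects (one per variant).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "pipeline.log")
  cat("", file = logfile)  # truncate
  .log_line(logfile, "reading baseline table: ", config$baseline)
  baseline <- read_baseline_table(config$baseline)
  mixed <- read_mixed_table(config$mixed)
  mixed_aug <- if (!is.null(config$mixed_augmented))
    read_mixed_table(config$mixed_augmented)

  classes <- NULL
  if (!is.null(config$fasta)) {
    refs <- read_hap_fasta(config$fasta)
    classes <- collapse_to_short_classes(refs, window = config$window)
    .log_line(logfile, "collapsed ", nrow(refs), " haplotypes into ",
              length(classes), " short-fragment classes")
  }
  harmonize_logged <- function(b, m) {
    withCallingHandlers(
      harmonize(b, m, classes = classes, orphans = config$orphans),
      warning = function(w) {
        .log_line(logfile, "orphan decision: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  fits <- list()
  for (v in config$variants) {
    vdir <- file.path(config$outdir, sprintf("variant%d", v))
    dir.create(vdir, showWarnings = FALSE)
    m <- if (v %in% c(3L, 4L) && !is.null(mixed_aug)) mixed_aug else mixed
    harm <- harmonize_logged(baseline, m)
    spec <- build_model(harm$baseline, harm$mixed, variant = v)
    if (length(spec$excluded) > 0L)
      .log_line(logfile, "variant ", v, ": excluded zero-transport ",
                "rookeries: ", paste(spec$excluded, collapse = ", "))
    .log_line(logfile, "variant ", v, ": fitting ", config$chains,
              " chains x ", config$iterations, " iterations (burn-in ",
              config$burn_in, ")")
    ft <- fit(spec, chains = config$chains, iterations = config$iterations,
              burn_in = config$burn_in, seed = config$seed)
    worst <- max(ft$convergence$Rhat)
    .log_line(logfile, "variant ", v, sprintf(": worst shrink factor %.4f (%s)",
              worst, if (ft$converged) "< 1.2" else ">= 1.2"))

    summ <- rbind(
      data.frame(level = "theta", group = ft$summary$theta$stock,
                 unit = ft$summary$theta$rookery,
                 ft$summary$theta[c("mean", "lower", "upper")]),
      data.frame(level = "phi", group = ft$summary$phi$rookery,
                 unit = ft$summary$phi$destination,
                 ft$summary$phi[c("mean", "lower", "upper")]))
    write.table(summ, file.path(vdir, "summary.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    write.table(ft$convergence, file.path(vdir, "convergence.csv"),
                sep = ",", row.names = FALSE, quote = TRUE)
    if (isTRUE(config$write_draws))
      .write_draws_csv(ft, file.path(vdir, "draws.csv"),
                       config$max_draw_rows)
    manifest <- list(
      variant = v, rookeries = spec$rookery_codes,
      stocks = spec$stock_codes, haplotypes = spec$haplotype_names,
      excluded = spec$excluded, dropped_orphans = harm$dropped,
      chains = config$chains, iterations = config$iterations,
      burn_in = config$burn_in, master_seed = config$seed,
      chain_seeds = ft$seeds, converged = ft$converged,
      inputs = list(baseline = config$baseline,
                    mixed = if (v %in% c(3L, 4L) &&
                                !is.null(config$mixed_augmented))
                      config$mixed_augmented else config$mixed,
                    fasta = config$fasta),
      window = config$window, orphans = config$orphans)
    jsonlite::write_json(manifest, file.path(vdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    fits[[sprintf("variant%d", v)]] <- ft
  }
  .log_line(logfile, "pipeline complete: ", length(fits), " variant(s)")
  invisible(fits)
}

# long columnar draws: chain, draw, parameter, value
.write_draws_csv <- function(ft, path, max_rows) {
  n <- dim(ft$chains[[1L]]$theta)[1L]
  thin <- max(1L, ceiling(n * length(ft$chains) / max_rows))
  keep <- seq(1L, n, by = thin)
  rows <- list()
  for (k in seq_along(ft$chains)) {
    ch <- ft$chains[[k]]
    for (m in seq_along(ch$stock_codes))
      for (r in seq_along(ch$rookery_codes))
        rows[[length(rows) + 1L]] <- data.frame(
          chain = k, draw = keep,
          parameter = sprintf("theta[%s,%s]", ch$stock_codes[m],
                              ch$rookery_codes[r]),
          value = ch$theta[keep, m, r])
    for (r in seq_along(ch$rookery_codes))
      for (d in seq_along(ch$destinations))
        rows[[length(rows) + 1L]] <- data.frame(
          chain = k, draw = keep,
          parameter = sprintf("phi[%s,%s]", ch$rookery_codes[r],
                              ch$destinations[d]),
          value = ch$phi[keep, r, d])
  }
  write.table(do.call(rbind, rows), path, sep = ",", row.names = FALSE,
              quote = TRUE)
}
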
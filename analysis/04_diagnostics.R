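#!/usr/bin/env Rscript

# Step 4: convergence assessment and a point-and-whisker contribution
# figure across the four fitted variants.

library(manymix)

vdirs <- Sys.glob("results/msa/variant*")
if (length(vdirs) == 0) stop("run analysis/03_fit_models.R first")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

summ <- do.call(rbind, lapply(vdirs, function(d) {
  s <- read.csv(file.path(d, "summary.csv"))
  s$variant <- basename(d)
  s
}))
conv <- do.call(rbind, lapply(vdirs, function(d) {
  cv <- read.csv(file.path(d, "convergence.csv"))
  cat(sprintf("%s: worst shrink factor %.4f (%s), %d/%d parameters < 1.2\n",
              basename(d), max(cv$Rhat),
              cv$parameter[which.max(cv$Rhat)],
              sum(cv$Rhat < 1.2), nrow(cv)))
  cv$variant <- basename(d)
  cv
}))
write.csv(conv, "results/figures/convergence_all.csv", row.names = FALSE)

th <- summ[summ$level == "theta", ]
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  gp <- ggplot(th, aes(x = unit, y = mean, colour = variant)) +
    geom_point(position = position_dodge(width = 0.6), size = 1) +
    geom_linerange(aes(ymin = lower, ymax = upper),
                   position = position_dodge(width = 0.6)) +
    facet_wrap(~group, ncol = 1) +
    labs(x = "rookery", y = "contribution (posterior mean, 95% CrI)") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
  ggsave("results/figures/contributions.pdf", gp, width = 9, height = 6)
  cat("figure written to results/figures/contributions.pdf\n")
} else {
  cat("ggplot2 not available; skipping the figure\n")
}
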
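#!/usr/bin/env Rscript
# Per-environment phenotypic analysis of the simulated trial: REML variance
# components with Wald significance, repeatability and CVe per trait and
# environment; the Shapiro-Wilk/Bartlett gate for combining environments;
# and fixed-hybrid BLUEs used downstream as the prediction response.

suppressPackageStartupMessages(library(bcnamScreen))

out <- "results/pheno"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
plots <- read_phenotypes("results/sim/phenotypes.csv")

vt <- varcomp_table(plots)
utils::write.csv(vt, file.path(out, "varcomp.csv"), row.names = FALSE)
print(vt[, c("trait", "environment", "sigma_h2", "sigma_r2", "sigma_e2",
             "pct_hybrid", "R", "cve_pct", "p_hybrid")], digits = 3)

res_by_env <- lapply(
  stats::setNames(unique(plots$environment), unique(plots$environment)),
  function(e) random_model_residuals(plots, "grain_yield", e))
gate <- combine_gate(res_by_env)
jsonlite::write_json(unclass(gate), file.path(out, "gate.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("combining gate: Shapiro-Wilk p = %.3g, Bartlett p = %.3g -> %s",
                gate$shapiro_p, gate$bartlett_p, gate$verdict))

blues <- do.call(rbind, lapply(unique(plots$trait), function(tr)
  do.call(rbind, lapply(unique(plots$environment), function(e)
    fit_blues(plots, tr, e)))))
utils::write.csv(blues, file.path(out, "blues.csv"), row.names = FALSE)
message(sprintf("wrote %d BLUEs (%d traits x %d environments)",
                nrow(blues), length(unique(plots$trait)),
                length(unique(plots$environment))))
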
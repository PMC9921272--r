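#!/usr/bin/env Rscript
# Marker-based relationships: MAF-filter the joint panel (lines + testers +
# founders), build additive and dominance GRMs, extend them to the hybrids
# by Kronecker products of the parental blocks, and run the two
# distance-based analyses (PCoA of IBS distance; regression of hybrid yield
# BLUEs on line distance to the donor parent).

suppressPackageStartupMessages(library(bcnamScreen))

out <- "results/kinship"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lines <- load_genotypes("results/sim/lines_dosage.tsv")
testers <- load_genotypes("results/sim/testers_dosage.tsv")
parents <- load_genotypes("results/sim/parents_dosage.tsv")
design <- utils::read.csv("results/sim/design.csv", stringsAsFactors = FALSE)
blues <- utils::read.csv("results/pheno/blues.csv", stringsAsFactors = FALSE)

panel <- maf_filter(rbind(lines, testers, parents))
message(sprintf("MAF filter: kept %d of %d markers",
                ncol(panel), ncol(lines)))

KA <- additive_grm(panel)
KD <- dominance_grm(panel)
sub <- function(K, ids) structure(unclass(K)[ids, ids],
                                  kind = attr(K, "kind"),
                                  class = "grm_kernel")
KA_h <- hybrid_kernel(sub(KA, rownames(lines)), sub(KA, rownames(testers)),
                      design)
KD_h <- hybrid_kernel(sub(KD, rownames(lines)), sub(KD, rownames(testers)),
                      design)
write_matrix_tsv(KA_h, file.path(out, "kernel_additive_hybrids.tsv"))
write_matrix_tsv(KD_h, file.path(out, "kernel_dominance_hybrids.tsv"))

D <- ibs_distance(panel)
write_matrix_tsv(D, file.path(out, "ibs_distance.tsv"))
pc <- pcoa(D)
utils::write.csv(
  data.frame(id = rownames(pc$coordinates), pc$coordinates[, 1:4]),
  file.path(out, "pcoa.csv"), row.names = FALSE)
message(sprintf("PCoA: first two axes carry %.1f%% + %.1f%% of the variance",
                pc$percent[1], pc$percent[2]))

# donor-distance vs hybrid grain yield, per environment: under the default
# generative model (many small QTL across the genome) no strong relationship
# is expected
dist_to_donor <- D[rownames(lines), "DONOR"]
dy <- lapply(unique(blues$environment), function(e) {
  b <- blues[blues$trait == "grain_yield" & blues$environment == e, ]
  dd <- design[match(b$hybrid, design$hybrid), ]
  keep <- !dd$is_check
  r <- distance_yield_regression(dist_to_donor[dd$line[keep]], b$blue[keep])
  message(sprintf("%s: r = %+.3f (R2 = %.3f, p = %.3g, n = %d)",
                  e, r$r, r$r_squared, r$p_slope, r$n))
  c(environment = e, r)
})
jsonlite::write_json(dy, file.path(out, "distance_yield.json"),
                     auto_unbox = TRUE, digits = NA)
message("outputs in ", out)
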
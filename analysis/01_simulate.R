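#!/usr/bin/env Rscript
# Simulate the default testcross trial: two BC1F3 populations (68 + 70
# lines) from a shared elite recurrent parent, crossed to two elite testers
# (143 experimental hybrids, 6 checks), phenotyped for grain yield, plant
# height and days to anthesis in two environments x two replicates.

suppressPackageStartupMessages(library(bcnamScreen))

seed <- 2026
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_trial(seed = seed)

write_genotypes_tsv(sim$lines$dosage, file.path(out, "lines_dosage.tsv"))
write_genotypes_tsv(sim$testers$dosage, file.path(out, "testers_dosage.tsv"))
parents <- rbind(RP = sim$founders$recurrent[1, ] * 2L,
                 DONOR = sim$founders$exotic[1, ] * 2L)
write_genotypes_tsv(parents, file.path(out, "parents_dosage.tsv"))
write_genotypes_vcf(sim$lines$dosage[1:10, 1:200],
                    file.path(out, "lines_head.vcf"),
                    map = sim$founders$map[1:200, ])
utils::write.csv(sim$design$hybrids, file.path(out, "design.csv"),
                 row.names = FALSE)
utils::write.csv(sim$phenotypes$plots, file.path(out, "phenotypes.csv"),
                 row.names = FALSE)
utils::write.csv(sim$phenotypes$truth, file.path(out, "truth.csv"),
                 row.names = FALSE)

dv <- divergent_markers(sim$founders)
message(sprintf("simulated %d experimental hybrids (+%d checks) on %d markers",
                n_experimental_hybrids(sim$design),
                sum(sim$design$hybrids$is_check), ncol(sim$lines$dosage)))
message(sprintf("mean exotic-allele fraction at donor-segregating loci: %.3f (theory 0.25)",
                mean(sim$pops[[1]]$dosage[, dv]) / 2))
message(sprintf("mean residual heterozygosity at those loci: %.3f (theory 0.125)",
                mean(sim$pops[[1]]$dosage[, dv] == 1)))
message("outputs in ", out)
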
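test_that("founders honour the divergence rule and map invariants", {
  f <- simulate_founders(100, 2, divergence = 1, seed = 1)
  expect_equal(length(divergent_markers(f)), 100)
  expect_true(all(f$recurrent == 0))
  expect_true(all(f$recurrent[1, ] == f$recurrent[2, ]))
  expect_true(all(f$exotic[1, ] == f$exotic[2, ]))

  f2 <- simulate_founders(1000, 10, divergence = 0.3, seed = 2)
  expect_equal(length(divergent_markers(f2)), 300)
  by_chrom <- split(f2$map$pos_cM, f2$map$chrom)
  expect_true(all(vapply(by_chrom, function(p) !is.unsorted(p), TRUE)))
  expect_true(all(f2$map$pos_cM >= 0))
  expect_false(anyDuplicated(f2$map$marker) > 0)

  expect_identical(simulate_founders(200, 5, 0.4, seed = 7),
                   simulate_founders(200, 5, 0.4, seed = 7))

  expect_error(simulate_founders(5, 10, 0.5), "n_markers")
  expect_error(simulate_founders(100, 10, 0), "divergence")
  expect_error(simulate_founders(100, 10, 1.2), "divergence")
})

test_that("meiosis passes homozygous parents through and respects linkage", {
  f <- simulate_founders(300, 3, 0.5, seed = 3)
  g <- meiosis(f$exotic, f$map, seed = 4)
  expect_identical(as.integer(g), as.integer(f$exotic[1, ]))

  # fully linked markers never recombine
  map0 <- data.frame(marker = c("a", "b"), chrom = 1L, pos_cM = c(50, 50))
  hap <- rbind(c(0L, 0L), c(1L, 1L))
  set.seed(5)
  rec0 <- replicate(500, { g <- meiosis(hap, map0); g[1] != g[2] })
  expect_false(any(rec0))

  expect_error(meiosis(hap, f$map), "does not match")
})

test_that("recombination fraction tracks Haldane's map function", {
  hap <- rbind(c(0L, 0L), c(1L, 1L))
  map50 <- data.frame(marker = c("a", "b"), chrom = 1L, pos_cM = c(0, 50))
  set.seed(6)
  rec <- mean(replicate(8000, { g <- meiosis(hap, map50); g[1] != g[2] }))
  expect_lt(abs(rec - 0.5 * (1 - exp(-2 * 0.5))), 0.016)  # ~3 binomial SE
})

test_that("BC1F3 lines meet Mendelian expectations at divergent loci", {
  f <- simulate_founders(400, 5, 0.5, seed = 8)
  pop <- simulate_bc1f3_population(f, 250, seed = 9)
  dv <- divergent_markers(f)
  # per-line summaries are independent across lines; 3-SE bands
  exotic_frac <- rowMeans(pop$dosage[, dv]) / 2
  expect_lt(abs(mean(exotic_frac) - 0.25),
            3 * sd(exotic_frac) / sqrt(length(exotic_frac)))
  het <- rowMeans(pop$dosage[, dv] == 1L)
  expect_lt(abs(mean(het) - 0.125), 3 * sd(het) / sqrt(length(het)))
  # non-divergent loci stay fixed for the recurrent allele
  expect_true(all(pop$dosage[, -dv] == 0))
  # dosage conservation
  expect_true(all(pop$dosage %in% 0:2))
})

test_that("identical founders give lines identical to the recurrent parent", {
  f <- simulate_founders(100, 2, 0.5, seed = 10)
  f$exotic <- f$recurrent  # no divergence at all
  pop <- simulate_bc1f3_population(f, 5, seed = 11)
  expect_true(all(pop$dosage == 0))
})

test_that("testcross hybrids combine one gamete from each parent", {
  f <- simulate_founders(200, 4, 0.6, seed = 12)
  pop <- simulate_bc1f3_population(f, 4, seed = 13)
  testers <- simulate_testers(f, n = 2, divergence = 0.2, seed = 14)
  # force a fully inbred line: make line 1 homozygous exotic-free
  pop$haplotypes[[1]] <- f$recurrent
  pop$dosage[1, ] <- 0L
  design <- data.frame(line = pop$ids[1], tester = testers$ids[1])
  hy <- make_testcross_hybrids(pop, testers, design, seed = 15)
  # inbred x inbred: heterozygous exactly where the parents differ
  tester_allele <- testers$haplotypes[[1]][1, ]
  expect_identical(as.integer(hy$dosage[1, ]), as.integer(tester_allele))
  expect_true(all(hy$dosage %in% 0:2))

  expect_error(
    make_testcross_hybrids(pop, testers,
                           data.frame(line = "nope", tester = testers$ids[1])),
    "unknown line")
})

test_that("default design reproduces the trial layout", {
  d <- default_trial_design(sprintf("A%02d", 1:68), sprintf("B%02d", 1:70),
                            c("T1", "T2"), check_ids = c("C1", "C2", "C3"))
  expect_equal(n_experimental_hybrids(d), 143)
  expect_equal(sum(d$hybrids$population == "POP2"), 75)
  expect_equal(sum(d$hybrids$is_check), 6)
  expect_false(anyDuplicated(d$hybrids$hybrid) > 0)
  # 5 dual-tester lines in population 2
  tab <- table(d$hybrids$line[d$hybrids$population == "POP2"])
  expect_equal(sum(tab == 2), 5)
})

test_that("phenotype generator follows the plot model exactly in edge cases", {
  sim <- small_trial()
  cfg0 <- list(flat = trait_effect_config(
    n_qtl = 10, add_sd = 0, dom_sd = 0, env_mean = c(CS = 5, BU = 7),
    sigma_r2 = 0, sigma_e2 = 0))
  ph <- simulate_phenotypes(sim$hybrids$dosage, cfg0, sim$design, seed = 16)
  expect_true(all(ph$plots$value[ph$plots$environment == "CS"] == 5))
  expect_true(all(ph$plots$value[ph$plots$environment == "BU"] == 7))

  # no error and no replicate variance: replicate plots identical
  cfg1 <- list(tr = trait_effect_config(
    n_qtl = 20, env_mean = c(CS = 0, BU = 0), sigma_r2 = 0, sigma_e2 = 0))
  ph1 <- simulate_phenotypes(sim$hybrids$dosage, cfg1, sim$design, seed = 17)
  w <- ph1$plots[ph1$plots$environment == "CS", ]
  v <- tapply(w$value, list(w$hybrid, w$replicate), identity)
  expect_equal(v[, 1], v[, 2])

  # truth decomposition is exact
  expect_equal(ph1$truth$g_total,
               ph1$truth$g_additive + ph1$truth$g_dominance)

  # determinism
  ph2 <- simulate_phenotypes(sim$hybrids$dosage, cfg1, sim$design, seed = 17)
  expect_identical(ph1, ph2)
})

test_that("realized-variance targets are planted exactly", {
  sim <- small_trial()
  cfg <- list(gy = trait_effect_config(
    n_qtl = 40, env_mean = c(CS = 10, BU = 10),
    sigma_r2 = 0.1, sigma_e2 = 0.5,
    target_var_a = c(CS = 1.5, BU = 0.9),
    target_var_d = c(CS = 0.5, BU = 0.3)))
  ph <- simulate_phenotypes(sim$hybrids$dosage, cfg, sim$design, seed = 18)
  tr_cs <- ph$truth[ph$truth$environment == "CS", ]
  expect_equal(var(tr_cs$g_additive), 1.5, tolerance = 1e-10)
  expect_equal(var(tr_cs$g_dominance), 0.5, tolerance = 1e-10)
  # orthogonal components: totals add
  expect_equal(var(tr_cs$g_total), 2.0, tolerance = 1e-8)
  tr_bu <- ph$truth[ph$truth$environment == "BU", ]
  expect_equal(var(tr_bu$g_additive), 0.9, tolerance = 1e-10)
})

test_that("plot-level variance decomposes by the law of total variance", {
  sim <- small_trial()
  vh <- 1.19; vr <- 0.15; ve <- 0.86
  cfg <- list(gy = trait_effect_config(
    n_qtl = 40, env_mean = c(CS = 6.3, BU = 6.3), sigma_r2 = vr,
    sigma_e2 = ve, target_var_a = 0.8 * vh, target_var_d = 0.2 * vh))
  set.seed(19)
  vals <- replicate(40, {
    ph <- simulate_phenotypes(sim$hybrids$dosage, cfg, sim$design)
    v <- ph$plots[ph$plots$environment == "BU", "value"]
    var(v)
  })
  expect_equal(mean(vals), vh + vr + ve, tolerance = 0.15)
})
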
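make_hwe_kernels <- function(n, m, seed) {
  set.seed(seed)
  p <- runif(m, 0.15, 0.85)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(M) <- list(sprintf("H%03d", seq_len(n)), sprintf("m%04d", seq_len(m)))
  list(M = M, KA = additive_grm(M), KD = dominance_grm(M))
}

test_that("constant response collapses onto the intercept", {
  k <- make_hwe_kernels(30, 100, seed = 1)
  y <- setNames(rep(5, 30), rownames(k$M))
  fit <- suppressWarnings(
    fit_gblup(y, k$KA, k$KD, n_iter = 2000, burn_in = 500, thin = 2, seed = 2))
  expect_equal(fit$mu, 5, tolerance = 0.05)
  expect_true(all(abs(fit$u_A) <= 3 * fit$u_A_sd + 1e-8))
  expect_true(all(abs(fit$u_D) <= 3 * fit$u_D_sd + 1e-8))
})

test_that("with fixed variances the sampler recovers the closed-form BLUP", {
  k <- make_hwe_kernels(20, 150, seed = 3)
  set.seed(4)
  uA <- draw_from_kernel(k$KA, 1)
  y <- setNames(uA + rnorm(20, 0, sqrt(0.5)), rownames(k$M))
  s2 <- list(sigma2_a = 1, sigma2_d = 0.3, sigma2_e = 0.5)
  fit <- fit_gblup(y, k$KA, k$KD, n_iter = 24000, burn_in = 4000, thin = 4,
                   seed = 5, fix_variances = s2)
  oracle <- mme_oracle(y, k$KA, k$KD, s2$sigma2_a, s2$sigma2_d, s2$sigma2_e)
  n_keep <- (24000 - 4000) / 4
  # 3 Monte-Carlo SEs per element, conservatively inflated for autocorrelation
  tolA <- 3 * fit$u_A_sd / sqrt(n_keep / 10)
  tolD <- 3 * fit$u_D_sd / sqrt(n_keep / 10)
  expect_true(all(abs(fit$u_A - oracle$u_A) < tolA))
  expect_true(all(abs(fit$u_D - oracle$u_D) < tolD))
  expect_equal(fit$mu, oracle$mu, tolerance = 0.05)
})

test_that("sampler output is deterministic given the seed", {
  k <- make_hwe_kernels(25, 100, seed = 6)
  set.seed(7)
  y <- setNames(rnorm(25), rownames(k$M))
  f1 <- fit_gblup(y, k$KA, k$KD, n_iter = 1500, burn_in = 500, thin = 2,
                  seed = 11)
  f2 <- fit_gblup(y, k$KA, k$KD, n_iter = 1500, burn_in = 500, thin = 2,
                  seed = 11)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$sigma2_a, f2$sigma2_a)
})

test_that("predictions respect kernel information", {
  k <- make_hwe_kernels(30, 120, seed = 8)
  set.seed(9)
  y <- setNames(rnorm(30, 10), rownames(k$M))
  fit <- fit_gblup(y, k$KA, k$KD, n_iter = 2000, burn_in = 500, thin = 2,
                   seed = 10)
  # targets in training predict at their fitted values
  expect_identical(predict(fit, names(y)[1:5]), fit$fitted[1:5])
  expect_error(predict(fit, "nope"), "unknown hybrid id")

  # a hybrid with zero covariance to everything predicts at the intercept
  KA0 <- rbind(cbind(unclass(k$KA), 0), 0)
  KA0[31, 31] <- 1e-10
  ids <- c(rownames(k$M), "ISOLATED")
  dimnames(KA0) <- list(ids, ids)
  KD0 <- KA0
  y2 <- c(y, ISOLATED = NA)
  fit0 <- fit_gblup(y2, KA0, KD0, n_iter = 2000, burn_in = 500, thin = 2,
                    seed = 12)
  expect_equal(unname(predict(fit0, "ISOLATED")), fit0$mu, tolerance = 1e-6)
})

test_that("held-out hybrids are predicted with useful accuracy at high h2", {
  rs <- sapply(1:6, function(s) {
    k <- make_hwe_kernels(300, 400, seed = 100 + s)
    set.seed(200 + s)
    g <- draw_from_kernel(k$KA, 1)
    y <- setNames(g + rnorm(300, 0, sqrt(var(g) / 9)), rownames(k$M))  # h2=0.9
    y_mask <- y
    test_ids <- rownames(k$M)[201:300]
    y_mask[test_ids] <- NA
    fit <- suppressWarnings(
      fit_gblup(y_mask, k$KA, k$KD, n_iter = 3000, burn_in = 1000,
                thin = 2, seed = s))
    cor(predict(fit, test_ids), g[201:300])
  })
  expect_gt(mean(rs), 0.6)
})

test_that("posterior summaries are exchangeable under hybrid reordering", {
  k <- make_hwe_kernels(40, 150, seed = 13)
  set.seed(14)
  y <- setNames(draw_from_kernel(k$KA, 1) + rnorm(40, 0, 0.5), rownames(k$M))
  fit1 <- fit_gblup(y, k$KA, k$KD, n_iter = 6000, burn_in = 2000, thin = 2,
                    seed = 15)
  perm <- sample(names(y))
  KAp <- sub_kernel(k$KA, perm); KDp <- sub_kernel(k$KD, perm)
  fit2 <- fit_gblup(y[perm], KAp, KDp, n_iter = 6000, burn_in = 2000,
                    thin = 2, seed = 16)
  # same posterior up to Monte-Carlo error (eigenbases differ numerically)
  expect_equal(fit2$fitted[names(y)], fit1$fitted,
               tolerance = 0.05)
  expect_equal(fit2$sigma2_a, fit1$sigma2_a, tolerance = 0.25)
})

test_that("the fit is not prior-dominated", {
  k <- make_hwe_kernels(120, 300, seed = 17)
  set.seed(18)
  y <- setNames(draw_from_kernel(k$KA, 1) + rnorm(120, 0, 0.6), rownames(k$M))
  # chains long enough that Monte-Carlo scatter is small next to the bound
  f_df5 <- fit_gblup(y, k$KA, k$KD, n_iter = 15000, burn_in = 5000, thin = 2,
                     seed = 19, priors = list(df = 5, R2 = 0.5))
  f_df10 <- fit_gblup(y, k$KA, k$KD, n_iter = 15000, burn_in = 5000, thin = 2,
                      seed = 19, priors = list(df = 10, R2 = 0.5))
  # typical (root-mean-square) prediction change stays under 0.1 SD(y)
  expect_lt(sqrt(mean((f_df5$fitted - f_df10$fitted)^2)), 0.1 * sd(y))
})

test_that("variance partition normalizes to 100 and flags weak chains", {
  k <- make_hwe_kernels(60, 200, seed = 20)
  set.seed(21)
  y <- setNames(draw_from_kernel(k$KA, 1) + rnorm(60, 0, 0.5), rownames(k$M))
  fit <- suppressWarnings(
    fit_gblup(y, k$KA, k$KD, n_iter = 4000, burn_in = 1000, thin = 2, seed = 22))
  vp <- suppressWarnings(variance_partition(fit))
  expect_equal(sum(vp$percent), 100, tolerance = 0.1)
  expect_true(all(vp$percent >= 0))
  # an absurdly short chain must warn, not fail
  short <- suppressWarnings(
    fit_gblup(y, k$KA, k$KD, n_iter = 220, burn_in = 100, thin = 2, seed = 23))
  expect_warning(variance_partition(short, ess_threshold = 1e6), "low effective")
})

test_that("a residual-dominated trait partitions mostly to error", {
  # h2 = 0.05: the residual should dominate the partition.  The trial is
  # scaled to ~600 hybrids because at low heritability the variance split
  # is informed only by the leading kernel eigendirections, and smaller
  # panels leave it prior-bound
  sim <- simulate_trial(n_markers = 1000, n_lines = c(300, 300), seed = 77,
                        configs = list(tr = trait_effect_config(
                          n_qtl = 10, env_mean = c(E1 = 0), sigma_r2 = 0,
                          sigma_e2 = 1)),
                        environments = "E1")
  ks <- hybrid_kernels(sim)
  shares <- sapply(1:4, function(s) {
    set.seed(400 + s)
    g <- draw_from_kernel(ks$additive, 1)
    y <- setNames(g + rnorm(length(g), 0, sqrt(19 * var(g))),
                  rownames(ks$additive))
    fit <- suppressWarnings(
      fit_gblup(y, ks$additive, ks$dominance, n_iter = 5000, burn_in = 2000,
                thin = 2, seed = s))
    suppressWarnings(variance_partition(fit))$percent[["residual"]]
  })
  expect_gt(mean(shares), 75)
})

test_that("effective-sample-size estimator behaves on known chains", {
  set.seed(24)
  iid <- rnorm(2000)
  expect_gt(ess(iid), 1000)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  expect_lt(ess(ar), 600)
  expect_equal(ess(rep(1, 50)), 50)
})
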
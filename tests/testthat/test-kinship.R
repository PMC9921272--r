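toy_panel <- function() {
  M <- rbind(L1 = c(0L, 0L), L2 = c(2L, 2L), L3 = c(1L, 1L))
  colnames(M) <- c("m1", "m2")
  M
}

test_that("MAF filter removes strictly-below-threshold markers only", {
  # frequencies 0, 0.05, 0.10, 0.50 across 10 individuals
  M <- cbind(a = rep(0L, 10),
             b = c(1L, rep(0L, 9)),
             c = c(2L, rep(0L, 9)),
             d = rep(1L, 10))
  rownames(M) <- sprintf("i%02d", 1:10)
  out <- maf_filter(M, 0.05)
  expect_identical(colnames(out), c("b", "c", "d"))  # p = 0.05 retained
  expect_equal(attr(out, "n_removed"), 1)

  # enumeration oracle on a wider toy
  set.seed(1)
  M2 <- sapply(c(0, 0.01, 0.04, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.02),
               function(p) {
                 k <- round(p * 100)
                 c(rep(1L, k), rep(0L, 100 - k))
               })
  colnames(M2) <- paste0("m", 1:10)
  rownames(M2) <- sprintf("i%03d", 1:100)
  p <- colMeans(M2) / 2
  by_hand <- sum(pmin(p, 1 - p) >= 0.05)
  expect_equal(ncol(maf_filter(M2, 0.05)), by_hand)

  M3 <- cbind(mono = rep(0L, 4)); rownames(M3) <- letters[1:4]
  expect_error(maf_filter(M3), "all markers removed")
})

test_that("additive GRM matches the hand-computed toy exactly", {
  K <- additive_grm(toy_panel())
  expected <- rbind(c(2, -2, 0), c(-2, 2, 0), c(0, 0, 0))
  dimnames(expected) <- list(c("L1", "L2", "L3"), c("L1", "L2", "L3"))
  expect_equal(unclass(K), expected, ignore_attr = TRUE)
  expect_equal(attr(K, "denominator"), 1)
})

test_that("additive GRM symmetries hold", {
  set.seed(2)
  M <- matrix(rbinom(30 * 50, 2, 0.4), 30, 50,
              dimnames = list(sprintf("i%02d", 1:30), sprintf("m%02d", 1:50)))
  K <- unclass(additive_grm(M))
  expect_lt(max(abs(K - t(K))), 1e-10)
  check_kernel_psd(K)

  # duplicate individual: identical rows/columns and K[i,i] == K[i,j]
  M2 <- rbind(M, dup = M[1, ])
  K2 <- unclass(additive_grm(M2))
  expect_equal(K2["i01", ], K2["dup", ], ignore_attr = TRUE)
  expect_equal(K2["i01", "i01"], K2["i01", "dup"])

  # marker permutation leaves K unchanged
  perm <- sample(ncol(M))
  expect_equal(unclass(additive_grm(M[, perm])), K, tolerance = 1e-12)

  # swapping reference/alternate labels at some markers leaves K unchanged
  M3 <- M
  flip <- c(3, 10, 20)
  M3[, flip] <- 2L - M3[, flip]
  expect_equal(unclass(additive_grm(M3)), K, tolerance = 1e-12)
})

test_that("dominance GRM uses the orthogonal heterosis coding", {
  # fully inbred panel at p = 0.5: W entries are -2 * 0.25 = -0.5
  M <- rbind(A = c(0L, 2L), B = c(2L, 0L))
  colnames(M) <- c("m1", "m2")
  KD <- dominance_grm(M)
  # W = [-0.5, -0.5; -0.5, -0.5], denom = 2 * (0.5)^2 = 0.5
  expect_equal(unclass(KD), matrix(1, 2, 2), ignore_attr = TRUE)

  # a single heterozygote at p = 0.5 gets W = 0.5 and the stated diagonal
  M2 <- rbind(A = 0L, B = 2L, H = 1L)
  colnames(M2) <- "m1"
  # p = 0.5 at the single marker: p = (0 + 2 + 1)/6 = 0.5
  KD2 <- dominance_grm(M2)
  denom <- (2 * 0.5 * 0.5)^2
  expect_equal(KD2["H", "H"], 0.25 / denom)

  M3 <- rbind(A = c(0L, 2L), B = c(0L, 2L))
  colnames(M3) <- c("m1", "m2")
  expect_error(dominance_grm(M3), "denominator")
})

test_that("additive and dominance kernels are near-orthogonal under HWE", {
  set.seed(3)
  n <- 400; m <- 800
  p <- runif(m, 0.1, 0.9)
  M <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(M) <- list(sprintf("i%03d", 1:n), sprintf("m%03d", 1:m))
  KA <- unclass(additive_grm(M)); KD <- unclass(dominance_grm(M))
  offd <- upper.tri(KA)
  # in-sample centering forces mean off-diagonal = -mean(diag)/(n-1); the
  # bound allows that structural term plus Monte-Carlo error
  structural <- mean(diag(KA)) / (n - 1)
  expect_lt(abs(mean(KA[offd])), structural + 3 * sd(KA[offd]) / sqrt(sum(offd)))
  expect_lt(abs(mean(KD[offd])),
            mean(diag(KD)) / (n - 1) + 3 * sd(KD[offd]) / sqrt(sum(offd)))
  prod_od <- KA[offd] * KD[offd]
  expect_lt(abs(mean(prod_od)),
            3 * sd(prod_od) / sqrt(length(prod_od)) + structural^2)
})

test_that("hybrid kernel factorizes into parental entries", {
  set.seed(4)
  KL <- structure(crossprod(matrix(rnorm(4), 2)), kind = "additive",
                  class = "grm_kernel")
  dimnames(KL) <- list(c("l1", "l2"), c("l1", "l2"))
  KT <- structure(crossprod(matrix(rnorm(4), 2)), kind = "additive",
                  class = "grm_kernel")
  dimnames(KT) <- list(c("t1", "t2"), c("t1", "t2"))
  grid <- expand.grid(line = c("l1", "l2"), tester = c("t1", "t2"),
                      stringsAsFactors = FALSE)
  grid$hybrid <- paste(grid$line, grid$tester, sep = ":")
  KH <- hybrid_kernel(KL, KT, grid)
  # all 16 entries against the direct Kronecker product
  kron <- kronecker(unclass(KT), unclass(KL))
  dimnames(kron) <- list(paste(grid$line, grid$tester, sep = ":"),
                         paste(grid$line, grid$tester, sep = ":"))
  expect_equal(unclass(KH), kron[grid$hybrid, grid$hybrid],
               ignore_attr = TRUE)

  # single tester with self-relationship 1: hybrid kernel equals line kernel
  KT1 <- structure(matrix(1, 1, 1, dimnames = list("t1", "t1")),
                   kind = "additive", class = "grm_kernel")
  g1 <- data.frame(line = c("l1", "l2"), tester = "t1",
                   hybrid = c("h1", "h2"))
  KH1 <- hybrid_kernel(KL, KT1, g1)
  expect_equal(unclass(KH1), unclass(KL), ignore_attr = TRUE)

  expect_error(hybrid_kernel(KL, KT, data.frame(line = "bad", tester = "t1",
                                                hybrid = "x")),
               "unknown line")
})

test_that("realized-subset hybrid kernel from the trial design is valid", {
  sim <- small_trial()
  ks <- hybrid_kernels(sim)
  expect_equal(dim(ks$additive), rep(nrow(sim$design$hybrids), 2))
  check_kernel_psd(unclass(ks$additive))
  check_kernel_psd(unclass(ks$dominance))
})

test_that("IBS distance obeys its per-locus share rule", {
  M <- rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L), c = c(2L, 2L, 2L),
             d = c(1L, 1L, 1L))
  colnames(M) <- paste0("m", 1:3)
  D <- ibs_distance(M)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
  expect_equal(D["a", "d"], 0.5)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0, d = 0))
  expect_equal(D, t(D))
})

test_that("IBS distance and additive GRM rank pairs consistently", {
  set.seed(5)
  M <- matrix(rbinom(5 * 40, 2, 0.5), 5, 40,
              dimnames = list(letters[1:5], sprintf("m%02d", 1:40)))
  D <- ibs_distance(M)
  K <- unclass(additive_grm(M))
  # brute-force per-locus share oracle
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    oracle[i, j] <- 1 - mean((2 - abs(M[i, ] - M[j, ])) / 2)
  expect_equal(unname(D), oracle, tolerance = 1e-12)
  od <- upper.tri(D)
  expect_lt(cor(D[od], K[od], method = "spearman"), 0)
})

test_that("PCoA round-trips planted configurations", {
  # three mutually equidistant points: equilateral triangle
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(D3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-8)
  emb <- as.matrix(dist(p3$coordinates))
  expect_lt(max(abs(emb - D3)), 1e-8)

  # planted 2-D configuration
  set.seed(6)
  XY <- cbind(runif(12), runif(12))
  rownames(XY) <- sprintf("p%02d", 1:12)
  D <- as.matrix(dist(XY))
  pr <- pcoa(D)
  expect_lt(max(abs(as.matrix(dist(pr$coordinates[, 1:2])) - D)), 1e-8)
  expect_equal(sum(pr$percent), 100, tolerance = 1e-8)
  expect_true(all(diff(pr$eigenvalues) <= 1e-12))

  # duplicated individual lands on identical coordinates
  D2 <- as.matrix(dist(XY[c(1, 1:12), ]))
  dimnames(D2) <- list(c("dup", rownames(XY)), c("dup", rownames(XY)))
  pr2 <- pcoa(D2)
  expect_equal(pr2$coordinates["dup", ], pr2$coordinates["p01", ],
               tolerance = 1e-8)

  expect_error(pcoa(matrix(0, 2, 2)), "at least 3")
})

test_that("distance-yield regression matches the closed-form OLS oracle", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  y <- 2 * x
  # summary.lm warns on the exact fit; expected for this fixture
  r <- suppressWarnings(distance_yield_regression(x, y))
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  set.seed(7)
  x4 <- c(0.05, 0.21, 0.33, 0.48)
  y4 <- c(5.2, 4.8, 6.1, 5.5)
  fit <- distance_yield_regression(x4, y4)
  # normal equations by hand
  slope <- sum((x4 - mean(x4)) * (y4 - mean(y4))) / sum((x4 - mean(x4))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y4) - slope * mean(x4), tolerance = 1e-12)

  expect_error(distance_yield_regression(rep(0.3, 5), rnorm(5)),
               "zero variance")
})

test_that("distance-yield regression is well-calibrated under the null", {
  set.seed(8)
  ps <- replicate(400, {
    x <- runif(70); y <- rnorm(70)
    distance_yield_regression(x, y)$p_slope
  })
  rs <- replicate(400, {
    x <- runif(70); y <- rnorm(70)
    distance_yield_regression(x, y)$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
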
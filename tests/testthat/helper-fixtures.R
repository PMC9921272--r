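# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Small complete trial: 2 x 30 lines, 500 markers, both environments.
small_trial <- function() {
  if (is.null(.fixtures$small_trial))
    .fixtures$small_trial <- simulate_trial(
      n_markers = 500, n_lines = c(30, 30), seed = 101)
  .fixtures$small_trial
}

sub_kernel <- function(K, ids) {
  structure(unclass(K)[ids, ids], kind = attr(K, "kind"),
            class = "grm_kernel")
}

# Additive + dominance hybrid kernels for a simulated trial.
hybrid_kernels <- function(sim) {
  panel <- maf_filter(rbind(sim$lines$dosage, sim$testers$dosage))
  KA <- additive_grm(panel)
  KD <- dominance_grm(panel)
  li <- rownames(sim$lines$dosage)
  ti <- rownames(sim$testers$dosage)
  list(
    additive = hybrid_kernel(sub_kernel(KA, li), sub_kernel(KA, ti),
                             sim$design$hybrids),
    dominance = hybrid_kernel(sub_kernel(KD, li), sub_kernel(KD, ti),
                              sim$design$hybrids))
}

# Draw a genetic-value vector u ~ N(0, K * s2) in the kernel's column space.
draw_from_kernel <- function(K, s2 = 1) {
  e <- eigen((unclass(K) + t(unclass(K))) / 2, symmetric = TRUE)
  keep <- e$values > 1e-8
  drop(e$vectors[, keep, drop = FALSE] %*%
         (stats::rnorm(sum(keep)) * sqrt(e$values[keep] * s2)))
}

# Balanced plot table: n_hyb hybrids x n_rep replicates, one environment.
balanced_plots <- function(n_hyb, n_rep, sigma_h2, sigma_r2, sigma_e2,
                           mu = 10, seed = 1, trait = "yield", env = "E1") {
  set.seed(seed)
  h <- rnorm(n_hyb, 0, sqrt(sigma_h2))
  r <- rnorm(n_rep, 0, sqrt(sigma_r2))
  do.call(rbind, lapply(seq_len(n_rep), function(j) {
    data.frame(hybrid = sprintf("H%03d", seq_len(n_hyb)),
               environment = env, replicate = paste0("rep", j),
               trait = trait,
               value = mu + h + r[j] + rnorm(n_hyb, 0, sqrt(sigma_e2)),
               stringsAsFactors = FALSE)
  }))
}

# Method-of-moments (balanced ANOVA) oracle for the two-random-effect model.
anova_varcomp_oracle <- function(plots) {
  wide <- with(plots, tapply(value, list(hybrid, replicate), identity))
  n_hyb <- nrow(wide); n_rep <- ncol(wide)
  grand <- mean(wide)
  ms_h <- n_rep * sum((rowMeans(wide) - grand)^2) / (n_hyb - 1)
  ms_r <- n_hyb * sum((colMeans(wide) - grand)^2) / (n_rep - 1)
  sse <- sum((wide - outer(rowMeans(wide), colMeans(wide), `+`) + grand)^2)
  mse <- sse / ((n_hyb - 1) * (n_rep - 1))
  c(sigma_h2 = max(0, (ms_h - mse) / n_rep),
    sigma_r2 = max(0, (ms_r - mse) / n_hyb),
    sigma_e2 = mse)
}

# BLUP of u_A and u_D with known variance components (closed form):
# mu_hat by GLS, E[u_k | y] = s2k * K_k %*% V^-1 (y - mu_hat).
mme_oracle <- function(y, K_A, K_D, s2a, s2d, s2e) {
  n <- length(y)
  V <- s2a * unclass(K_A) + s2d * unclass(K_D) + diag(s2e, n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  r <- y - mu
  list(mu = mu,
       u_A = drop(s2a * unclass(K_A) %*% Vi %*% r),
       u_D = drop(s2d * unclass(K_D) %*% Vi %*% r))
}
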
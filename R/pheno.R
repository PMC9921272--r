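#' Per-environment REML variance components for a testcross trial
#'
#' Fits the two-random-effect model for a single environment,
#' \deqn{y = 1\mu + Z_1 h + Z_2 r + \varepsilon,}
#' with hybrid effects h ~ N(0, sigma_h^2), replicate effects
#' r ~ N(0, sigma_r^2) and residuals N(0, sigma_e^2), by REML (via lme4).
#' Reports the three components, their percent of total, a one-sided Wald
#' p-value for the hybrid variance (z = estimate / SE, SE from the inverse
#' numerical Hessian of the restricted log-likelihood at the optimum),
#' entry-mean repeatability and the residual coefficient of variation.
#'
#' @param plots plot-level data.frame (columns hybrid, environment,
#'   replicate, trait, value).
#' @param trait trait name to analyse.
#' @param environment environment id to analyse.
#' @param test "wald" (default), "lrt" for a 0.5*chisq(0) + 0.5*chisq(1)
#'   mixture likelihood-ratio test of sigma_h^2 = 0, or "none" to skip the
#'   significance test (estimates only).
#' @return a list of class \code{varcomp_result}: sigma_h2, sigma_r2,
#'   sigma_e2, pct (named, sums to 100), p_hybrid, wald_z, R (entry-mean
#'   repeatability at the environment's replicate number), cve_pct, mean,
#'   n_plots, n_hybrids, n_reps, flags (character).
#' @export
fit_random_model <- function(plots, trait, environment,
                             test = c("wald", "lrt", "none")) {
  test <- match.arg(test)
  d <- plots[plots$trait == trait & plots$environment == environment, ]
  if (!nrow(d)) stop("no plots for ", trait, " in ", environment)
  if (any(!is.finite(d$value))) stop("non-finite phenotype values")
  n_hyb <- length(unique(d$hybrid))
  n_rep <- length(unique(d$replicate))
  if (n_hyb < 2) stop("need >= 2 hybrids")
  flags <- character()
  if (n_rep < 2) flags <- c(flags, "single_replicate")

  if (stats::var(d$value) == 0) {
    pct <- c(hybrid = NA_real_, replicate = NA_real_, residual = NA_real_)
    return(structure(list(sigma_h2 = 0, sigma_r2 = 0, sigma_e2 = 0,
                          pct = pct, p_hybrid = NA_real_, wald_z = NA_real_,
                          R = NA_real_, cve_pct = 0, mean = mean(d$value),
                          n_plots = nrow(d), n_hybrids = n_hyb, n_reps = n_rep,
                          flags = c(flags, "degenerate_constant")),
                     class = "varcomp_result"))
  }

  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ (1 | hybrid) + (1 | replicate), data = d, REML = TRUE,
               control = lme4::lmerControl(
                 optimizer = "bobyqa",
                 check.conv.singular = "ignore",
                 optCtrl = list(rhoend = 2e-9)))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  s_h <- get_vc("hybrid"); s_r <- get_vc("replicate")
  s_e <- vc$vcov[vc$grp == "Residual"]
  if (s_h < 0 || s_r < 0) flags <- c(flags, "negative_component_truncated")
  s_h <- max(s_h, 0); s_r <- max(s_r, 0)
  tot <- s_h + s_r + s_e
  pct <- 100 * c(hybrid = s_h, replicate = s_r, residual = s_e) / tot

  wz <- NA_real_; p <- NA_real_
  if (test == "wald") {
    se <- tryCatch(
      varcomp_wald_se(d$value, d$hybrid, d$replicate, c(s_h, s_r, s_e)),
      error = function(e) rep(NA_real_, 3))
    if (is.finite(se[1]) && se[1] > 0) {
      wz <- s_h / se[1]
      p <- stats::pnorm(wz, lower.tail = FALSE)
    } else flags <- c(flags, "wald_se_unavailable")
  } else if (test == "lrt") {
    fit0 <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ (1 | replicate), data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    lrt <- max(0, 2 * (stats::logLik(fit) - stats::logLik(fit0)))
    # 0.5*chisq(0) + 0.5*chisq(1) boundary mixture
    p <- if (lrt == 0) 1 else 0.5 * stats::pchisq(lrt, df = 1,
                                                  lower.tail = FALSE)
  }

  mu <- mean(d$value)
  res <- structure(list(
    sigma_h2 = s_h, sigma_r2 = s_r, sigma_e2 = s_e, pct = pct,
    p_hybrid = p, wald_z = wz,
    R = repeatability(s_h, s_e, n_rep),
    cve_pct = cve(s_e, mu),
    mean = mu, n_plots = nrow(d), n_hybrids = n_hyb, n_reps = n_rep,
    flags = flags), class = "varcomp_result")
  attr(res, "lmer_fit") <- fit
  res
}

# Restricted log-likelihood of the two-random-effect model at variance
# components vc = (sigma_h2, sigma_r2, sigma_e2); used only for the Wald
# standard error (numerical Hessian at the lme4 optimum).
reml_loglik_2rf <- function(vc, y, hybrid, replicate) {
  n <- length(y)
  Z1 <- stats::model.matrix(~ 0 + factor(hybrid))
  Z2 <- stats::model.matrix(~ 0 + factor(replicate))
  V <- vc[1] * tcrossprod(Z1) + vc[2] * tcrossprod(Z2) + diag(vc[3], n)
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vi_1)
  beta <- sum(Vi_y) / xvx
  r <- y - beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (logdetV + log(xvx) + sum(r * Vi_r))
}

varcomp_wald_se <- function(y, hybrid, replicate, est) {
  est <- pmax(est, 1e-10)
  H <- stats::optimHess(est, function(v) {
    if (any(v <= 0)) return(-1e10)
    reml_loglik_2rf(v, y, hybrid, replicate)
  })
  cov <- solve(-H)
  sqrt(pmax(diag(cov), 0))
}

#' Entry-mean repeatability
#'
#' R = sigma_h^2 / (sigma_h^2 + sigma_e^2 / r): the proportion of variance
#' among hybrid entry means (averaged over r replicates) attributable to
#' genetic differences among hybrids.
#'
#' @param sigma_h2 hybrid variance component.
#' @param sigma_e2 residual variance component.
#' @param n_replicates number of replicates the entry means average over.
#' @return repeatability in [0, 1]; NA when both components are zero.
#' @export
repeatability <- function(sigma_h2, sigma_e2, n_replicates) {
  stopifnot(n_replicates >= 1, sigma_h2 >= 0, sigma_e2 >= 0)
  denom <- sigma_h2 + sigma_e2 / n_replicates
  if (denom == 0) return(NA_real_)
  sigma_h2 / denom
}

#' Residual coefficient of variation
#'
#' CVe = 100 * sqrt(sigma_e2) / trait mean, in percent.
#'
#' @param sigma_e2 residual variance component.
#' @param trait_mean trait mean (must be positive).
#' @return CVe in percent.
#' @export
cve <- function(sigma_e2, trait_mean) {
  stopifnot(sigma_e2 >= 0)
  if (trait_mean <= 0) stop("trait mean must be positive for CVe")
  100 * sqrt(sigma_e2) / trait_mean
}

#' Best linear unbiased estimates of hybrid means
#'
#' Refits the single-environment model with hybrid as a fixed effect and
#' replicate random, and returns the generalized-least-squares hybrid
#' estimates.  In a balanced complete design these equal the hybrid means
#' across replicates; with missing plots they are the GLS solution under the
#' model's REML replicate/residual variances.
#'
#' @inheritParams fit_random_model
#' @return data.frame (hybrid, trait, environment, blue).
#' @export
fit_blues <- function(plots, trait, environment) {
  d <- plots[plots$trait == trait & plots$environment == environment, ]
  if (!nrow(d)) stop("no plots for ", trait, " in ", environment)
  if (any(!is.finite(d$value))) stop("non-finite phenotype values")
  d$hybrid <- factor(d$hybrid)
  if (nlevels(d$hybrid) == 1) {
    # a lone hybrid carries no replicate contrast: BLUE is its plot mean
    out <- data.frame(hybrid = levels(d$hybrid), trait = trait,
                      environment = environment, blue = mean(d$value),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ 0 + hybrid + (1 | replicate), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  b <- lme4::fixef(fit)
  names(b) <- sub("^hybrid", "", names(b))
  out <- data.frame(hybrid = names(b), trait = trait,
                    environment = environment, blue = unname(b),
                    stringsAsFactors = FALSE)
  attr(out, "lmer_fit") <- fit
  out
}

#' Environment-combining gate
#'
#' Decides whether per-environment analyses may be pooled: Shapiro-Wilk on
#' the pooled residuals (normality), Bartlett's test across environments
#' (homogeneity of residual variances), and the two-group variance-ratio F
#' (largest over smallest residual variance).  The verdict is
#' "keep-separate" if either Shapiro-Wilk or Bartlett rejects at
#' \code{alpha}.
#'
#' @param residuals_by_env named list of residual vectors, one per
#'   environment (>= 3 values each).
#' @param alpha significance level for the verdict.
#' @return list of class \code{combine_gate_report}: shapiro_W, shapiro_p,
#'   bartlett_stat, bartlett_p, f_stat, f_df, f_p, verdict.
#' @export
combine_gate <- function(residuals_by_env, alpha = 0.05) {
  if (length(residuals_by_env) < 2) stop("need >= 2 environments")
  if (any(vapply(residuals_by_env, length, 1L) < 3))
    stop("need >= 3 residuals per environment")
  pooled <- unlist(residuals_by_env, use.names = FALSE)
  sw <- stats::shapiro.test(pooled)
  bt <- stats::bartlett.test(residuals_by_env)
  v <- vapply(residuals_by_env, stats::var, 1)
  hi <- which.max(v); lo <- which.min(v)
  n <- vapply(residuals_by_env, length, 1L)
  f <- v[hi] / v[lo]
  df <- c(n[hi] - 1L, n[lo] - 1L)
  f_p <- 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE)
  f_p <- min(1, f_p)
  verdict <- if (sw$p.value < alpha || bt$p.value < alpha)
    "keep-separate" else "combine"
  structure(list(shapiro_W = unname(sw$statistic),
                 shapiro_p = sw$p.value,
                 bartlett_stat = unname(bt$statistic),
                 bartlett_p = bt$p.value,
                 f_stat = unname(f), f_df = unname(df), f_p = unname(f_p),
                 verdict = verdict),
            class = "combine_gate_report")
}

#' Residuals of the per-environment random model
#'
#' @inheritParams fit_random_model
#' @return numeric vector of conditional residuals.
#' @export
random_model_residuals <- function(plots, trait, environment) {
  vc <- fit_random_model(plots, trait, environment)
  fit <- attr(vc, "lmer_fit")
  if (is.null(fit)) stop("degenerate fit has no residuals")
  unname(stats::residuals(fit))
}

#' Table of variance components across traits and environments
#'
#' Runs \code{\link{fit_random_model}} for every trait x environment in the
#' plot table and assembles the Table-1-style summary.
#'
#' @param plots plot-level data.frame.
#' @return data.frame with one row per trait x environment.
#' @export
varcomp_table <- function(plots) {
  combos <- unique(plots[, c("trait", "environment")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    vc <- fit_random_model(plots, combos$trait[i], combos$environment[i])
    data.frame(trait = combos$trait[i], environment = combos$environment[i],
               sigma_h2 = vc$sigma_h2, sigma_r2 = vc$sigma_r2,
               sigma_e2 = vc$sigma_e2,
               pct_hybrid = vc$pct[["hybrid"]],
               pct_replicate = vc$pct[["replicate"]],
               pct_residual = vc$pct[["residual"]],
               p_hybrid = vc$p_hybrid, R = vc$R, cve_pct = vc$cve_pct,
               mean = vc$mean, n_plots = vc$n_plots, n_reps = vc$n_reps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
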
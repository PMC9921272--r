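#' Bayesian GBLUP with additive and dominance kernels
#'
#' Fits the hybrid-prediction model
#' \deqn{y = \mu + u_A + u_D + \varepsilon,}
#' with u_A ~ N(0, K_A sigma_A^2), u_D ~ N(0, K_D sigma_D^2) and
#' i.i.d. residuals, by Gibbs sampling.  Each kernel is eigendecomposed once
#' and its effects are sampled in the eigenbasis, where the full conditional
#' is diagonal; variance components get scaled-inverse-chi-squared priors
#' whose scales split a prior R^2 between the additive and dominance terms.
#' Hybrids with missing phenotypes are handled by posterior-predictive
#' augmentation, so cross-validation needs no refitting machinery: their
#' predictions are the posterior mean of mu + u_A + u_D.
#'
#' @param y named numeric vector of phenotypes (typically per-environment
#'   BLUEs), NA for hybrids to predict.  Names must match the kernel ids.
#' @param K_A,K_D additive and dominance kernels over all hybrids in
#'   \code{y} (row/col names matching \code{names(y)}).
#' @param priors list: \code{df} (degrees of freedom, default 5),
#'   \code{R2} (prior proportion of variance explained jointly by the two
#'   genetic terms, default 0.5, split equally).
#' @param n_iter,burn_in,thin MCMC settings (defaults 15000 / 5000 / 5).
#' @param seed integer seed; same seed and inputs give identical summaries.
#' @param fix_variances optional named list (sigma2_a, sigma2_d, sigma2_e);
#'   when supplied the variance updates are skipped and these values used
#'   throughout (used for exact-conditional checks).
#' @param keep_trace keep the thinned scalar chains (mu and variances) in
#'   the result (default TRUE; needed for diagnostics).
#' @return object of class \code{gblup_fit}: posterior means/SDs of mu,
#'   u_A, u_D, variance components, fitted values (= predictions for all
#'   ids), ESS diagnostics, and the settings used.
#' @export
fit_gblup <- function(y, K_A, K_D, priors = list(df = 5, R2 = 0.5),
                      n_iter = 15000, burn_in = 5000, thin = 5,
                      seed = 1, fix_variances = NULL, keep_trace = TRUE) {
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by hybrid id")
  if (is.null(rownames(K_A)) || is.null(rownames(K_D)))
    stop("kernels must carry hybrid ids")
  if (!all(ids %in% rownames(K_A)) || !all(ids %in% rownames(K_D)))
    stop("kernel ids do not cover the phenotyped/target hybrids")
  obs <- which(!is.na(y))
  if (!length(obs)) stop("no phenotyped hybrids overlap the kernels")
  if (any(!is.finite(y[obs]))) stop("non-finite phenotypes")
  n <- length(y)
  KA <- unclass(K_A)[ids, ids]
  KD <- unclass(K_D)[ids, ids]

  eig_basis <- function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values)))
      stop("kernel not PSD beyond jitter")
    keep <- e$values > 1e-8
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep],
         mean_diag = mean(diag(K)))
  }
  EA <- eig_basis(KA)
  ED <- eig_basis(KD)

  df <- if (is.null(priors$df)) 5 else priors$df
  R2 <- if (is.null(priors$R2)) 0.5 else priors$R2
  stopifnot(df > 0, R2 > 0, R2 < 1)
  vy <- stats::var(y[obs])
  if (vy == 0) vy <- 1e-8  # constant response: vague but proper scales
  S_a <- vy * (R2 / 2) / max(EA$mean_diag, 1e-12) * (df + 2) / df
  S_d <- vy * (R2 / 2) / max(ED$mean_diag, 1e-12) * (df + 2) / df
  S_e <- vy * (1 - R2) * (df + 2) / df

  fixed <- !is.null(fix_variances)
  s2a <- if (fixed) fix_variances$sigma2_a else vy * R2 / 2 / max(EA$mean_diag, 1e-12)
  s2d <- if (fixed) fix_variances$sigma2_d else vy * R2 / 2 / max(ED$mean_diag, 1e-12)
  s2e <- if (fixed) fix_variances$sigma2_e else vy * (1 - R2)

  set.seed(seed)
  mu <- mean(y[obs])
  uA <- numeric(n); uD <- numeric(n)
  ycur <- y
  ycur[-obs] <- mu
  miss <- setdiff(seq_len(n), obs)

  n_keep <- length(seq(burn_in + 1L, n_iter, by = thin))
  sum_u <- list(A = numeric(n), D = numeric(n))
  sq_u <- list(A = numeric(n), D = numeric(n))
  sum_pred <- numeric(n); sq_pred <- numeric(n)
  tr <- matrix(NA_real_, n_keep, 4,
               dimnames = list(NULL, c("mu", "sigma2_a", "sigma2_d", "sigma2_e")))
  kept <- 0L

  draw_kernel <- function(E, r, s2k, s2e) {
    rt <- drop(crossprod(E$U, r))
    prec <- 1 / s2e + 1 / (E$d * s2k)
    alpha <- rt / s2e / prec + stats::rnorm(length(rt)) / sqrt(prec)
    list(alpha = alpha, u = drop(E$U %*% alpha))
  }

  for (it in seq_len(n_iter)) {
    e0 <- ycur - uA - uD
    mu <- mean(e0) + stats::rnorm(1) * sqrt(s2e / n)

    dA <- draw_kernel(EA, ycur - mu - uD, s2a, s2e)
    uA <- dA$u
    dD <- draw_kernel(ED, ycur - mu - uA, s2d, s2e)
    uD <- dD$u

    if (!fixed) {
      s2a <- (sum(dA$alpha^2 / EA$d) + df * S_a) /
        stats::rchisq(1, df + length(EA$d))
      s2d <- (sum(dD$alpha^2 / ED$d) + df * S_d) /
        stats::rchisq(1, df + length(ED$d))
      e_all <- ycur - mu - uA - uD
      s2e <- (sum(e_all^2) + df * S_e) / stats::rchisq(1, df + n)
    }
    if (length(miss))
      ycur[miss] <- mu + uA[miss] + uD[miss] +
        stats::rnorm(length(miss)) * sqrt(s2e)

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      pred <- mu + uA + uD
      sum_u$A <- sum_u$A + uA; sq_u$A <- sq_u$A + uA^2
      sum_u$D <- sum_u$D + uD; sq_u$D <- sq_u$D + uD^2
      sum_pred <- sum_pred + pred; sq_pred <- sq_pred + pred^2
      tr[kept, ] <- c(mu, s2a, s2d, s2e)
    }
  }

  post_sd <- function(s, sq) sqrt(pmax(sq / kept - (s / kept)^2, 0))
  u_A_mean <- sum_u$A / kept; u_D_mean <- sum_u$D / kept
  fitted <- sum_pred / kept
  names(u_A_mean) <- names(u_D_mean) <- names(fitted) <- ids

  ess_vals <- apply(tr, 2, ess)
  if (!fixed && any(ess_vals[2:4] < 100))
    warning("effective sample size below 100 for a variance component; ",
            "consider longer chains")

  structure(list(
    ids = ids,
    mu = mean(tr[, "mu"]), mu_sd = stats::sd(tr[, "mu"]),
    u_A = u_A_mean, u_A_sd = post_sd(sum_u$A, sq_u$A),
    u_D = u_D_mean, u_D_sd = post_sd(sum_u$D, sq_u$D),
    sigma2_a = mean(tr[, "sigma2_a"]), sigma2_d = mean(tr[, "sigma2_d"]),
    sigma2_e = mean(tr[, "sigma2_e"]),
    fitted = fitted, fitted_sd = post_sd(sum_pred, sq_pred),
    mean_diag = c(additive = EA$mean_diag, dominance = ED$mean_diag),
    ess = ess_vals,
    observed = ids[obs],
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = seed, df = df, R2 = R2, fixed = fixed),
    trace = if (keep_trace) tr else NULL),
    class = "gblup_fit")
}

#' Predict hybrid values from a GBLUP fit
#'
#' Posterior predictive mean mu + u_A + u_D for the requested hybrids; ids
#' must have been present in the kernels at fit time (phenotyped or not).
#'
#' @param object a \code{gblup_fit}.
#' @param target_ids hybrid ids to predict (default: all).
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.gblup_fit <- function(object, target_ids = NULL, ...) {
  if (is.null(target_ids)) target_ids <- object$ids
  unknown <- setdiff(target_ids, object$ids)
  if (length(unknown)) stop("unknown hybrid id: ", unknown[1])
  object$fitted[target_ids]
}

#' Partition phenotypic variance from a GBLUP fit
#'
#' Scales each posterior-mean variance component by the mean diagonal of its
#' kernel (the sample variance its random effect contributes) and normalizes
#' with the residual to percentages.
#'
#' @param fit a \code{gblup_fit}.
#' @param ess_threshold minimum effective sample size per variance chain
#'   below which a warning (not an error) is raised.
#' @return list of class \code{variance_partition}: \code{percent} (named:
#'   additive, dominance, residual; sums to 100) and \code{components}.
#' @export
variance_partition <- function(fit, ess_threshold = 100) {
  stopifnot(inherits(fit, "gblup_fit"))
  low <- fit$ess[c("sigma2_a", "sigma2_d", "sigma2_e")] < ess_threshold
  if (any(low))
    warning("low effective sample size for: ",
            paste(names(low)[low], collapse = ", "))
  comp <- c(additive = fit$sigma2_a * fit$mean_diag[["additive"]],
            dominance = fit$sigma2_d * fit$mean_diag[["dominance"]],
            residual = fit$sigma2_e)
  structure(list(percent = 100 * comp / sum(comp), components = comp),
            class = "variance_partition")
}

#' Effective sample size of an MCMC chain
#'
#' Geyer's initial positive sequence estimator: the autocovariances are
#' summed in consecutive pairs until a pair-sum turns non-positive.
#'
#' @param x numeric chain.
#' @return effective sample size (capped at \code{length(x)}).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 1000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  m <- floor((length(ac) - 1) / 2)
  s <- 0
  for (k in seq_len(m)) {
    pair <- ac[2 * k] + ac[2 * k + 1]
    if (pair <= 0) break
    s <- s + pair
  }
  min(n, n / (1 + 2 * s))
}
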
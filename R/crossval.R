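#' Selection-accuracy metrics for genomic prescreening
#'
#' Three metrics used to judge whether predictions can screen testcross
#' hybrids: the Pearson correlation between predicted and observed values,
#' the fraction of the observed top \code{top_frac} recovered in the
#' predicted top set (selection accuracy), and the fraction of the observed
#' bottom \code{bottom_frac} recovered in the predicted bottom set
#' (elimination accuracy).  Set sizes use round-half-away-from-zero with a
#' floor of 1; rank ties are broken deterministically by id order.
#'
#' @param predicted,observed equal-length numeric vectors (n >= 3).
#' @param ids optional ids used for deterministic tie-breaking (default:
#'   position).
#' @param top_frac,bottom_frac selected/eliminated fractions (defaults 0.15
#'   and 0.50).
#' @return list: \code{r} (NA when either vector has zero variance),
#'   \code{top_acc}, \code{bottom_acc}, \code{k_top}, \code{k_bottom}.
#' @export
selection_metrics <- function(predicted, observed, ids = NULL,
                              top_frac = 0.15, bottom_frac = 0.50) {
  n <- length(predicted)
  stopifnot(length(observed) == n, n >= 3)
  if (anyNA(predicted) || anyNA(observed)) stop("missing values in metrics")
  if (is.null(ids)) ids <- seq_len(n)

  round_half_up <- function(x) floor(x + 0.5)
  k_top <- max(1L, round_half_up(top_frac * n))
  k_bot <- max(1L, round_half_up(bottom_frac * n))

  top_set <- function(x, k) order(-x, ids)[seq_len(k)]
  bot_set <- function(x, k) order(x, ids)[seq_len(k)]

  r <- if (stats::var(predicted) == 0 || stats::var(observed) == 0)
    NA_real_ else stats::cor(predicted, observed)
  list(
    r = r,
    top_acc = length(intersect(top_set(predicted, k_top),
                               top_set(observed, k_top))) / k_top,
    bottom_acc = length(intersect(bot_set(predicted, k_bot),
                                  bot_set(observed, k_bot))) / k_bot,
    k_top = k_top, k_bottom = k_bot)
}

cv_summarize <- function(per_rep) {
  agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                       se = stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  do.call(rbind, lapply(split(per_rep, per_rep[, setdiff(names(per_rep),
                                                         c("repetition", "metric", "value")),
                                               drop = FALSE]), function(g) {
    out <- lapply(split(g$value, g$metric), agg)
    data.frame(g[1, setdiff(names(g), c("repetition", "metric", "value")),
                 drop = FALSE],
               metric = names(out),
               mean = vapply(out, `[[`, 1, "mean"),
               se = vapply(out, `[[`, 1, "se"),
               row.names = NULL)
  }))
}

#' Intrapopulation cross-validation (CV1)
#'
#' Repeatedly splits the experimental hybrids at random into a training half
#' and a validation half, fits the additive+dominance GBLUP on the training
#' BLUEs, predicts the validation hybrids, and scores the three selection
#' metrics on the validation set.  When population labels are supplied the
#' split is stratified so both populations stay represented in training.
#'
#' @param blues named numeric vector of per-environment hybrid BLUEs.
#' @param K_A,K_D hybrid kernels covering all ids in \code{blues}.
#' @param population optional named factor/character of population labels
#'   (names matching \code{blues}) used for stratified splitting.
#' @param train_frac training fraction (default 0.5).
#' @param reps repetitions (default 20).
#' @param seed integer seed; repetition i uses seed + i.
#' @param mcmc list overriding the sampler settings (n_iter, burn_in, thin).
#' @param top_frac,bottom_frac metric fractions.
#' @return list of class \code{cv_report}: \code{per_rep} (long data.frame:
#'   scheme, repetition, metric, value) and \code{summary} (mean and SE per
#'   metric, SE = SD/sqrt(reps)).
#' @export
run_cv1 <- function(blues, K_A, K_D, population = NULL, train_frac = 0.5,
                    reps = 20, seed = 1,
                    mcmc = list(n_iter = 15000, burn_in = 5000, thin = 5),
                    top_frac = 0.15, bottom_frac = 0.50) {
  ids <- names(blues)
  if (length(ids) < 10) stop("need >= 10 hybrids with BLUEs")
  strata <- if (is.null(population)) rep("all", length(ids)) else {
    stopifnot(all(ids %in% names(population)))
    as.character(population[ids])
  }
  rows <- list()
  splits <- list()
  for (i in seq_len(reps)) {
    set.seed(seed + i)
    train <- unlist(lapply(split(ids, strata), function(g) {
      sample(g, max(1L, floor(train_frac * length(g))))
    }), use.names = FALSE)
    if (length(train) < 5) stop("training set smaller than 5")
    valid <- setdiff(ids, train)
    splits[[i]] <- list(train = train, valid = valid)
    y <- blues
    y[valid] <- NA
    fit <- fit_gblup(y, K_A, K_D, n_iter = mcmc$n_iter,
                     burn_in = mcmc$burn_in, thin = mcmc$thin,
                     seed = seed + i)
    m <- selection_metrics(predict(fit, valid), blues[valid], ids = valid,
                           top_frac = top_frac, bottom_frac = bottom_frac)
    rows[[i]] <- data.frame(scheme = "CV1", repetition = i,
                            metric = c("r", "top_acc", "bottom_acc"),
                            value = c(m$r, m$top_acc, m$bottom_acc),
                            stringsAsFactors = FALSE)
  }
  per_rep <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(per_rep = per_rep, summary = cv_summarize(per_rep),
                 splits = splits),
            class = "cv_report")
}

#' Interpopulation cross-validation with graded target inclusion (CV3)
#'
#' Trains on all of the base population plus a fraction f of the target
#' population and predicts the remaining target hybrids, for
#' f in \code{fractions} (at f = 0 the training set is the base population
#' alone: pure across-population prediction).  Metrics are computed on the
#' held-out target hybrids only.
#'
#' @inheritParams run_cv1
#' @param population named labels (names matching \code{blues}); exactly the
#'   two populations \code{base} and \code{target} are used.
#' @param base,target population labels: training source and prediction
#'   target.
#' @param fractions inclusion fractions of the target population in training
#'   (default c(0, 0.05, 0.10, 0.20)); the included count is
#'   \code{floor(f * n_target)}.
#' @return \code{cv_report} whose rows carry the inclusion fraction.
#' @export
run_cv3 <- function(blues, K_A, K_D, population, base, target,
                    fractions = c(0, 0.05, 0.10, 0.20), reps = 20, seed = 1,
                    mcmc = list(n_iter = 15000, burn_in = 5000, thin = 5),
                    top_frac = 0.15, bottom_frac = 0.50) {
  ids <- names(blues)
  stopifnot(all(ids %in% names(population)), base != target)
  pop <- as.character(population[ids])
  base_ids <- ids[pop == base]
  target_ids <- ids[pop == target]
  if (!length(base_ids)) stop("no hybrids in base population")
  if (length(target_ids) < 10) stop("target population smaller than 10")
  stopifnot(all(fractions >= 0), all(fractions < 1))

  rows <- list()
  splits <- list()
  for (f in fractions) {
    n_inc <- floor(f * length(target_ids))
    for (i in seq_len(reps)) {
      set.seed(seed + i)
      included <- if (n_inc > 0) sample(target_ids, n_inc) else character()
      train <- c(base_ids, included)
      valid <- setdiff(target_ids, included)
      splits[[paste(f, i)]] <- list(fraction = f, train = train,
                                    valid = valid)
      y <- blues
      y[valid] <- NA
      fit <- fit_gblup(y, K_A, K_D, n_iter = mcmc$n_iter,
                       burn_in = mcmc$burn_in, thin = mcmc$thin,
                       seed = seed + i)
      m <- selection_metrics(predict(fit, valid), blues[valid], ids = valid,
                             top_frac = top_frac, bottom_frac = bottom_frac)
      rows[[paste(f, i)]] <- data.frame(
        scheme = "CV3", fraction = f, repetition = i,
        metric = c("r", "top_acc", "bottom_acc"),
        value = c(m$r, m$top_acc, m$bottom_acc),
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(per_rep = per_rep, summary = cv_summarize(per_rep),
                 splits = splits),
            class = "cv_report")
}
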
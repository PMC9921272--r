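#' Trait effect configuration for the phenotype generator
#'
#' Describes one trait's genetic architecture and trial noise structure.
#' Causal loci are a random subset of the genotyped markers; additive effects
#' act on the centred dosage and dominance effects on the heterozygote
#' indicator.  When \code{target_var_a}/\code{target_var_d} are supplied
#' (optionally as named per-environment vectors) the drawn effects are
#' rescaled so the realized additive/dominance variance across the trial's
#' hybrids equals the requested value — the standard device for planting a
#' known variance structure in a simulated trial.
#'
#' @param n_qtl number of causal loci.
#' @param add_sd,dom_sd standard deviations of the raw additive and dominance
#'   effect draws.
#' @param env_mean named numeric vector: trait mean per environment.
#' @param sigma_r2 replicate (block) variance, per environment if named.
#' @param sigma_e2 plot-error variance, per environment if named.
#' @param target_var_a,target_var_d optional realized additive/dominance
#'   variance across hybrids (scalar or named per environment); NULL leaves
#'   the raw draws unscaled.
#' @param hidden_qtl_frac fraction of causal loci flagged as un-genotyped in
#'   the returned bookkeeping (for robustness studies); effects still act.
#' @return a list of class \code{trait_effect_config}.
#' @export
trait_effect_config <- function(n_qtl = 60, add_sd = 1, dom_sd = 0.5,
                                env_mean, sigma_r2, sigma_e2,
                                target_var_a = NULL, target_var_d = NULL,
                                hidden_qtl_frac = 0) {
  stopifnot(n_qtl >= 1, all(sigma_r2 >= 0), all(sigma_e2 >= 0),
            hidden_qtl_frac >= 0, hidden_qtl_frac < 1)
  structure(list(n_qtl = n_qtl, add_sd = add_sd, dom_sd = dom_sd,
                 env_mean = env_mean, sigma_r2 = sigma_r2,
                 sigma_e2 = sigma_e2, target_var_a = target_var_a,
                 target_var_d = target_var_d,
                 hidden_qtl_frac = hidden_qtl_frac),
            class = "trait_effect_config")
}

#' Default trait configurations for a two-environment sorghum testcross trial
#'
#' Grain yield (t/ha), plant height (cm) and days to anthesis with
#' per-environment means and variance structure matching a rainfed College
#' Station-like environment ("CS") and a limited-irrigation Bushland-like
#' environment ("BU"): e.g. grain yield in BU has hybrid/replicate/residual
#' variances 1.19/0.15/0.86 and mean 6.3 t/ha.  Additive variance carries
#' ~80% of the genetic target, dominance ~20%.
#'
#' @return named list of \code{trait_effect_config} objects.
#' @export
default_trait_configs <- function() {
  cfg <- function(env_mean, vh, vr, ve, n_qtl = 60) {
    trait_effect_config(
      n_qtl = n_qtl,
      env_mean = env_mean,
      sigma_r2 = vr, sigma_e2 = ve,
      target_var_a = 0.8 * vh, target_var_d = 0.2 * vh
    )
  }
  list(
    grain_yield = cfg(env_mean = c(CS = 8.1, BU = 6.3),
                      vh = c(CS = 0.28, BU = 1.19),
                      vr = c(CS = 0.09, BU = 0.15),
                      ve = c(CS = 0.65, BU = 0.86)),
    plant_height = cfg(env_mean = c(CS = 142.8, BU = 125.4),
                       vh = c(CS = 142.9, BU = 41.4),
                       vr = c(CS = 1.3, BU = 8.9),
                       ve = c(CS = 45.4, BU = 65.4)),
    days_to_anthesis = cfg(env_mean = c(CS = 79.2, BU = 71.3),
                           vh = c(CS = 4.91, BU = 4.07),
                           vr = c(CS = 0.06, BU = 0.002),
                           ve = c(CS = 2.03, BU = 1.47))
  )
}

env_param <- function(x, env) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (!env %in% names(x)) stop("no parameter for environment ", env)
  unname(x[env])
}

#' Simulate plot-level phenotypes for a testcross trial
#'
#' Generates plot records under the randomized-complete-block generative
#' model: plot value = environment mean + genetic value + replicate effect +
#' plot error, with replicate effects Normal(0, sigma_r2) per
#' environment-replicate and errors i.i.d. Normal(0, sigma_e2).  The genetic
#' value of a hybrid decomposes exactly into an additive part (centred-dosage
#' regression on causal loci) and a dominance deviation (heterozygote
#' indicator), both recorded per hybrid and environment in the truth table.
#'
#' @param hybrid_dosage n_hybrids x m dosage matrix (rownames are hybrid ids).
#' @param configs named list of \code{trait_effect_config}, one per trait.
#' @param design a \code{trial_design}.
#' @param seed optional seed.
#' @return list with \code{plots} (data.frame: hybrid, line, tester,
#'   population, environment, replicate, trait, value) and \code{truth}
#'   (data.frame: hybrid, trait, environment, g_additive, g_dominance,
#'   g_total), plus \code{causal} bookkeeping per trait.
#' @export
simulate_phenotypes <- function(hybrid_dosage, configs, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(design, "trial_design"))
  hy <- design$hybrids
  missing_g <- setdiff(hy$hybrid, rownames(hybrid_dosage))
  if (length(missing_g))
    stop("no genotype for hybrid ", missing_g[1])
  X <- hybrid_dosage[hy$hybrid, , drop = FALSE]
  n <- nrow(X)

  plots <- list()
  truth <- list()
  causal <- list()
  for (trait in names(configs)) {
    cf <- configs[[trait]]
    if (cf$n_qtl > ncol(X)) stop("more causal loci than markers")
    qtl <- sort(sample.int(ncol(X), cf$n_qtl))
    a <- stats::rnorm(cf$n_qtl, 0, cf$add_sd)
    d <- stats::rnorm(cf$n_qtl, 0, cf$dom_sd)
    Xq <- X[, qtl, drop = FALSE]
    xbar <- colMeans(Xq)
    g_a_raw <- drop(sweep(Xq, 2, xbar) %*% a)
    g_d_raw <- drop((Xq == 1L) %*% d)
    g_d_raw <- g_d_raw - mean(g_d_raw)
    # dominance deviations are orthogonal to additive values by definition;
    # project out the additive direction so planted variances add exactly
    if (stats::var(g_a_raw) > 0)
      g_d_raw <- g_d_raw -
        g_a_raw * stats::cov(g_d_raw, g_a_raw) / stats::var(g_a_raw)
    hidden <- if (cf$hidden_qtl_frac > 0)
      sample(qtl, floor(cf$hidden_qtl_frac * cf$n_qtl)) else integer()
    causal[[trait]] <- list(qtl = qtl, a = a, d = d, hidden = hidden)

    rescale <- function(g_raw, target, env) {
      if (is.null(target)) return(g_raw)
      tv <- env_param(target, env)
      v <- stats::var(g_raw)
      if (tv > 0 && v == 0)
        stop("cannot scale a zero-variance genetic component to ", tv)
      if (tv == 0) return(g_raw * 0)
      g_raw * sqrt(tv / v)
    }

    for (env in design$environments) {
      g_a <- rescale(g_a_raw, cf$target_var_a, env)
      g_d <- rescale(g_d_raw, cf$target_var_d, env)
      g <- g_a + g_d
      truth[[paste(trait, env)]] <- data.frame(
        hybrid = hy$hybrid, trait = trait, environment = env,
        g_additive = g_a, g_dominance = g_d, g_total = g,
        stringsAsFactors = FALSE)

      mu <- env_param(cf$env_mean, env)
      s_r2 <- env_param(cf$sigma_r2, env)
      s_e2 <- env_param(cf$sigma_e2, env)
      for (rep_i in seq_len(design$replicates)) {
        r_eff <- stats::rnorm(1, 0, sqrt(s_r2))
        plots[[paste(trait, env, rep_i)]] <- data.frame(
          hybrid = hy$hybrid, line = hy$line, tester = hy$tester,
          population = hy$population, environment = env,
          replicate = paste0("rep", rep_i), trait = trait,
          value = mu + g + r_eff + stats::rnorm(n, 0, sqrt(s_e2)),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(plots = do.call(rbind, c(plots, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       causal = causal)
}

#' Simulate a complete testcross trial
#'
#' Convenience wrapper: founders, two BC1F3 populations, testers, check
#' lines, the default trial design, hybrid genotypes and phenotypes, in one
#' call.  Defaults reproduce the study conditions this package targets: two
#' populations of 68 and 70 lines from a shared recurrent parent, two elite
#' testers, 5 dual-tester lines (143 experimental hybrids), 3 check lines
#' (6 check hybrids), two environments with two replicates, 2,000 markers on
#' 10 chromosomes.
#'
#' @param n_markers,n_chromosomes,divergence founder settings.
#' @param n_lines integer vector of length 2: lines per population.
#' @param tester_divergence elite-pool divergence of testers/checks from the
#'   recurrent parent.
#' @param configs trait configurations (default \code{default_trait_configs}).
#' @param environments,replicates trial layout.
#' @param seed integer seed controlling the whole simulation.
#' @return list: \code{founders}, \code{pops} (list of two bc_populations),
#'   \code{lines} (bound), \code{testers}, \code{checks}, \code{design},
#'   \code{hybrids} (dosage + design), \code{phenotypes} (plots + truth).
#' @export
simulate_trial <- function(n_markers = 2000, n_chromosomes = 10,
                           divergence = 0.3, n_lines = c(68, 70),
                           tester_divergence = 0.15,
                           configs = default_trait_configs(),
                           environments = c("CS", "BU"), replicates = 2,
                           seed = 1) {
  set.seed(seed)
  founders <- simulate_founders(n_markers, n_chromosomes, divergence)
  pop1 <- simulate_bc1f3_population(founders, n_lines[1], id_prefix = "P1L")
  pop2 <- simulate_bc1f3_population(founders, n_lines[2], id_prefix = "P2L")
  testers <- simulate_testers(founders, n = 2, divergence = tester_divergence,
                              id_prefix = "T")
  checks <- simulate_testers(founders, n = 3, divergence = tester_divergence,
                             id_prefix = "CHK")
  design <- default_trial_design(pop1$ids, pop2$ids, testers$ids, checks$ids,
                                 pop_names = c("POP1", "POP2"),
                                 environments = environments,
                                 replicates = replicates)
  lines <- bind_populations(pop1, pop2, checks)
  hybrids <- make_testcross_hybrids(lines, testers, design$hybrids)
  phen <- simulate_phenotypes(hybrids$dosage, configs, design)
  list(founders = founders, pops = list(pop1, pop2), lines = lines,
       testers = testers, checks = checks, design = design,
       hybrids = hybrids, phenotypes = phen)
}
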
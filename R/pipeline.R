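#' Default pipeline configuration
#'
#' Returns the configuration the end-to-end screening pipeline runs with:
#' simulate the default trial (two BC1F3 populations of 68 and 70 lines,
#' two testers, 143 experimental hybrids, two environments x two
#' replicates), analyse every trait per environment, and run genomic
#' prediction and both cross-validation schemes on grain yield.
#'
#' @param out_dir output directory.
#' @param seed global seed; each stage uses seed + a fixed stage counter so
#'   stages can be rerun independently yet reproducibly.
#' @return a list of class \code{pipeline_config}.
#' @export
default_pipeline_config <- function(out_dir = "bcnam_run", seed = 1) {
  structure(list(
    simulate = list(n_markers = 2000, n_chromosomes = 10, divergence = 0.3,
                    n_lines = c(68, 70), tester_divergence = 0.15),
    input = NULL,
    maf_threshold = 0.05,
    gp_trait = "grain_yield",
    mcmc = list(n_iter = 15000, burn_in = 5000, thin = 5),
    cv = list(reps = 20, train_frac = 0.5,
              fractions = c(0, 0.05, 0.10, 0.20),
              base = "POP1", target = "POP2"),
    out_dir = out_dir,
    seed = seed), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks that either simulation parameters or existing input paths are
#' supplied, and that numeric settings are in range, before any stage runs.
#'
#' @param config a \code{pipeline_config} (or plain list).
#' @return the config, invisibly; errors on the first problem found.
#' @export
validate_config <- function(config) {
  if (is.null(config$simulate) && is.null(config$input))
    stop("config needs either simulation parameters or input paths")
  if (!is.null(config$input)) {
    for (f in unlist(config$input))
      if (!file.exists(f)) stop("input path does not exist: ", f)
  }
  stopifnot(config$maf_threshold >= 0, config$maf_threshold <= 0.5,
            config$mcmc$n_iter > config$mcmc$burn_in,
            config$cv$reps >= 1)
  invisible(config)
}

stage_seed <- function(config, stage) {
  # counter-based expansion of the global seed; order is fixed
  counters <- c(simulate = 1L, pheno = 2L, kinship = 3L, gblup = 4L,
                cv = 5L)
  config$seed + unname(counters[stage])
}

#' Run the end-to-end screening pipeline
#'
#' Executes the stages in dependency order — simulate (or load), phenotypic
#' analysis (variance components, combining gate, BLUEs), kinship (MAF
#' filter, additive/dominance GRMs, hybrid kernels, IBS distance, PCoA,
#' distance-vs-yield regression), genomic prediction (GBLUP fit and variance
#' partition per environment) and cross-validation (CV1 and CV3) — writing
#' each stage's outputs under \code{config$out_dir} before dependents run,
#' and finally a manifest with per-file checksums.
#'
#' @param config a \code{pipeline_config}; see
#'   \code{\link{default_pipeline_config}}.
#' @return the manifest (list), invisibly; files under \code{out_dir}.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  log_line <- function(...) message("[bcnamScreen] ", ...)

  ## stage 1: simulate or load -------------------------------------------
  if (!is.null(config$simulate)) {
    log_line("stage simulate (seed ", stage_seed(config, "simulate"), ")")
    sim <- do.call(simulate_trial,
                   c(config$simulate, list(seed = stage_seed(config, "simulate"))))
    plots <- sim$phenotypes$plots
    design <- sim$design$hybrids
    hybrid_dosage <- sim$hybrids$dosage
    line_dosage <- sim$lines$dosage
    tester_dosage <- sim$testers$dosage
    parent_dosage <- rbind(
      RP = sim$founders$recurrent[1, ] * 2L,
      DONOR = sim$founders$exotic[1, ] * 2L)
    utils::write.csv(plots, emit(file.path(out, "phenotypes.csv")),
                     row.names = FALSE)
    utils::write.csv(sim$phenotypes$truth, emit(file.path(out, "truth.csv")),
                     row.names = FALSE)
    write_genotypes_tsv(line_dosage, emit(file.path(out, "lines_dosage.tsv")))
    utils::write.csv(design, emit(file.path(out, "design.csv")),
                     row.names = FALSE)
  } else {
    log_line("stage load")
    line_dosage <- load_genotypes(config$input$line_genotypes)
    tester_dosage <- load_genotypes(config$input$tester_genotypes)
    hybrid_dosage <- if (!is.null(config$input$hybrid_genotypes))
      load_genotypes(config$input$hybrid_genotypes) else NULL
    plots <- read_phenotypes(config$input$phenotypes, config$input$column_map)
    design <- utils::read.csv(config$input$design, stringsAsFactors = FALSE)
    parent_dosage <- NULL
  }
  environments <- sort(unique(plots$environment))
  traits <- unique(plots$trait)

  ## stage 2: phenotypic analysis ----------------------------------------
  log_line("stage pheno")
  vt <- varcomp_table(plots)
  utils::write.csv(vt, emit(file.path(out, "varcomp.csv")), row.names = FALSE)
  res_by_env <- lapply(stats::setNames(environments, environments),
                       function(e) random_model_residuals(plots, traits[1], e))
  gate <- combine_gate(res_by_env)
  jsonlite::write_json(unclass(gate), emit(file.path(out, "gate.json")),
                       auto_unbox = TRUE, digits = NA)
  blues <- do.call(rbind, lapply(traits, function(tr)
    do.call(rbind, lapply(environments, function(e) fit_blues(plots, tr, e)))))
  utils::write.csv(blues, emit(file.path(out, "blues.csv")), row.names = FALSE)

  ## stage 3: kinship ----------------------------------------------------
  log_line("stage kinship")
  panel <- rbind(line_dosage, tester_dosage,
                 if (!is.null(parent_dosage)) parent_dosage)
  panel <- maf_filter(panel, config$maf_threshold)
  KA_panel <- additive_grm(panel)
  KD_panel <- dominance_grm(panel)
  line_ids <- rownames(line_dosage)
  tester_ids <- rownames(tester_dosage)
  sub_kernel <- function(K, ids)
    structure(unclass(K)[ids, ids], kind = attr(K, "kind"),
              class = "grm_kernel")
  KA_line <- sub_kernel(KA_panel, line_ids)
  KA_tester <- sub_kernel(KA_panel, tester_ids)
  KD_line <- sub_kernel(KD_panel, line_ids)
  KD_tester <- sub_kernel(KD_panel, tester_ids)
  KA_hyb <- hybrid_kernel(KA_line, KA_tester, design)
  KD_hyb <- hybrid_kernel(KD_line, KD_tester, design)
  write_matrix_tsv(KA_hyb, emit(file.path(out, "kernel_additive_hybrids.tsv")))
  write_matrix_tsv(KD_hyb, emit(file.path(out, "kernel_dominance_hybrids.tsv")))

  D <- ibs_distance(panel)
  write_matrix_tsv(D, emit(file.path(out, "ibs_distance.tsv")))
  pc <- pcoa(D)
  pc_df <- data.frame(id = rownames(pc$coordinates),
                      pc$coordinates[, 1:min(4, ncol(pc$coordinates))],
                      check.names = FALSE)
  utils::write.csv(pc_df, emit(file.path(out, "pcoa.csv")), row.names = FALSE)

  dy <- NULL
  if (!is.null(parent_dosage) && config$gp_trait %in% traits) {
    dist_to_donor <- D[line_ids, "DONOR"]
    dy <- lapply(stats::setNames(environments, environments), function(e) {
      b <- blues[blues$trait == config$gp_trait & blues$environment == e, ]
      bx <- stats::setNames(b$blue, b$hybrid)
      dd <- design[match(names(bx), design$hybrid), ]
      keep <- !is.na(dd$line) & dd$line %in% line_ids &
        (!"is_check" %in% names(dd) | !isTRUE(dd$is_check))
      distance_yield_regression(dist_to_donor[dd$line[keep]], bx[keep])
    })
    jsonlite::write_json(dy, emit(file.path(out, "distance_yield.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  ## stage 4: genomic prediction -----------------------------------------
  log_line("stage gblup (seed ", stage_seed(config, "gblup"), ")")
  exp_ids <- design$hybrid[if ("is_check" %in% names(design))
    !design$is_check else rep(TRUE, nrow(design))]
  partitions <- list()
  blues_by_env <- list()
  for (e in environments) {
    b <- blues[blues$trait == config$gp_trait & blues$environment == e, ]
    yb <- stats::setNames(b$blue, b$hybrid)
    yb <- yb[names(yb) %in% exp_ids]
    blues_by_env[[e]] <- yb
    fit <- fit_gblup(yb, KA_hyb, KD_hyb,
                     n_iter = config$mcmc$n_iter,
                     burn_in = config$mcmc$burn_in, thin = config$mcmc$thin,
                     seed = stage_seed(config, "gblup"))
    vp <- variance_partition(fit)
    partitions[[e]] <- data.frame(environment = e,
                                  component = names(vp$percent),
                                  percent = unname(vp$percent))
    preds <- data.frame(hybrid = names(fit$fitted), environment = e,
                        prediction = unname(fit$fitted))
    utils::write.csv(preds,
                     emit(file.path(out, paste0("gblup_pred_", e, ".csv"))),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, partitions),
                   emit(file.path(out, "variance_partition.csv")),
                   row.names = FALSE)

  ## stage 5: cross-validation -------------------------------------------
  log_line("stage cv (seed ", stage_seed(config, "cv"), ")")
  pop_lab <- stats::setNames(design$population, design$hybrid)
  cv_rows <- list()
  for (e in environments) {
    yb <- blues_by_env[[e]]
    cv1 <- run_cv1(yb, KA_hyb, KD_hyb, population = pop_lab[names(yb)],
                   train_frac = config$cv$train_frac, reps = config$cv$reps,
                   seed = stage_seed(config, "cv"), mcmc = config$mcmc)
    cv1$per_rep$environment <- e
    cv_rows[[paste0("cv1_", e)]] <- cv1$per_rep
    cv3 <- run_cv3(yb, KA_hyb, KD_hyb, population = pop_lab[names(yb)],
                   base = config$cv$base, target = config$cv$target,
                   fractions = config$cv$fractions, reps = config$cv$reps,
                   seed = stage_seed(config, "cv"), mcmc = config$mcmc)
    cv3$per_rep$environment <- e
    cv_rows[[paste0("cv3_", e)]] <- cv3$per_rep
  }
  cv_all <- do.call(rbind, lapply(cv_rows, function(d) {
    if (!"fraction" %in% names(d)) d$fraction <- NA_real_
    d[, c("scheme", "environment", "fraction", "repetition", "metric", "value")]
  }))
  rownames(cv_all) <- NULL
  utils::write.csv(cv_all, emit(file.path(out, "cv_metrics.csv")),
                   row.names = FALSE)

  ## manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("bcnamScreen")),
    seed = config$seed,
    stage_seeds = as.list(vapply(c("simulate", "pheno", "kinship", "gblup",
                                   "cv"),
                                 function(s) stage_seed(config, s), 1)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    settings = list(maf_threshold = config$maf_threshold,
                    mcmc = config$mcmc, cv = config$cv,
                    maf_boundary = "MAF exactly at threshold retained",
                    k_rounding = "round half away from zero, floor 1"),
    checksums = as.list(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
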
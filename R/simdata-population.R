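#' Simulate a BC1F3 introgression population
#'
#' Follows the single-plant-descent scheme a backcross nursery uses: for each
#' line, F1 = recurrent x exotic; a BC1F1 plant is formed from one F1 gamete
#' and one recurrent-parent gamete; the BC1F2 and BC1F3 plants are each
#' produced by self-pollinating the previous plant (two independent gametes).
#' At markers where the parents differ, the expected exotic-allele frequency
#' is 0.25 and the expected BC1F3 heterozygosity is 0.125 (0.5 at BC1F1,
#' halved at each of the two selfing generations).
#'
#' @param founders a \code{founder_pair} from \code{\link{simulate_founders}}.
#' @param n_lines number of lines to derive (each from an independent BC1
#'   plant).
#' @param id_prefix prefix for line ids.
#' @param seed optional seed.
#' @return an object of class \code{bc_population}: list with \code{dosage}
#'   (n_lines x m integer matrix, count of the exotic allele in {0,1,2}),
#'   \code{haplotypes} (list of 2 x m matrices, the BC1F3 plant of each line),
#'   \code{map}, and \code{ids}.
#' @export
simulate_bc1f3_population <- function(founders, n_lines, id_prefix = "L",
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(founders, "founder_pair"), n_lines >= 1)
  map <- validate_map(founders$map)
  m <- nrow(map)
  f1 <- rbind(founders$recurrent[1, ], founders$exotic[1, ])

  ids <- sprintf("%s%03d", id_prefix, seq_len(n_lines))
  haplos <- vector("list", n_lines)
  dosage <- matrix(0L, n_lines, m, dimnames = list(ids, map$marker))
  for (i in seq_len(n_lines)) {
    bc1f1 <- rbind(meiosis(f1, map), meiosis(founders$recurrent, map))
    bc1f2 <- self_plant(bc1f1, map)
    bc1f3 <- self_plant(bc1f2, map)
    haplos[[i]] <- bc1f3
    dosage[i, ] <- bc1f3[1, ] + bc1f3[2, ]
  }
  structure(list(dosage = dosage, haplotypes = haplos, map = map, ids = ids),
            class = "bc_population")
}

#' Simulate elite inbred testers (or elite check lines)
#'
#' Elite-pool inbreds are modelled as fully homozygous lines that differ from
#' the recurrent parent at a random fraction of markers; they stand in for the
#' male-sterile A-line testers and the elite R-line checks of a testcross
#' trial.
#'
#' @param founders a \code{founder_pair} (supplies the map and the recurrent
#'   parent haplotype).
#' @param n number of inbreds.
#' @param divergence fraction of markers at which each inbred differs from the
#'   recurrent parent.
#' @param id_prefix prefix for ids.
#' @param seed optional seed.
#' @return a \code{bc_population}-shaped object (dosage is the count of the
#'   non-recurrent allele; haplotypes homozygous).
#' @export
simulate_testers <- function(founders, n = 2, divergence = 0.15,
                             id_prefix = "T", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(founders, "founder_pair"), n >= 1,
            divergence >= 0, divergence <= 1)
  map <- founders$map
  m <- nrow(map)
  ids <- sprintf("%s%d", id_prefix, seq_len(n))
  n_div <- floor(divergence * m)
  haplos <- vector("list", n)
  dosage <- matrix(0L, n, m, dimnames = list(ids, map$marker))
  for (i in seq_len(n)) {
    allele <- integer(m)
    allele[sample.int(m, n_div)] <- 1L
    haplos[[i]] <- matrix(rep(allele, each = 2), nrow = 2,
                          dimnames = list(NULL, map$marker))
    dosage[i, ] <- 2L * allele
  }
  structure(list(dosage = dosage, haplotypes = haplos, map = map, ids = ids),
            class = "bc_population")
}

#' Make testcross hybrid genotypes
#'
#' Each hybrid is line x tester: one gamete sampled from the (possibly still
#' heterozygous) BC1F3 line plus one gamete from the homozygous tester.  One
#' gamete is drawn per hybrid id — a hybrid is treated as a single genotype,
#' so residual line heterozygosity enters through that one sampled gamete.
#'
#' @param lines a \code{bc_population} of candidate lines (may be the
#'   concatenation of several populations; see \code{\link{bind_populations}}).
#' @param testers a \code{bc_population} of testers.
#' @param design data.frame with columns \code{line} and \code{tester}; one
#'   row per hybrid.  Hybrid ids are \code{line:tester} unless a
#'   \code{hybrid} column is supplied.
#' @param seed optional seed.
#' @return list with \code{dosage} (n_hybrids x m matrix, alternate-allele
#'   dosage in {0,1,2}) and \code{design} (with a \code{hybrid} id column).
#' @export
make_testcross_hybrids <- function(lines, testers, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("line", "tester") %in% names(design)))
  unknown_l <- setdiff(design$line, lines$ids)
  if (length(unknown_l)) stop("unknown line in design: ", unknown_l[1])
  unknown_t <- setdiff(design$tester, testers$ids)
  if (length(unknown_t)) stop("unknown tester in design: ", unknown_t[1])

  if (is.null(design$hybrid))
    design$hybrid <- paste(design$line, design$tester, sep = ":")
  if (anyDuplicated(design$hybrid)) stop("duplicate hybrid ids in design")

  map <- lines$map
  m <- nrow(map)
  dosage <- matrix(0L, nrow(design), m,
                   dimnames = list(design$hybrid, map$marker))
  for (i in seq_len(nrow(design))) {
    lg <- meiosis(lines$haplotypes[[match(design$line[i], lines$ids)]], map)
    tg <- meiosis(testers$haplotypes[[match(design$tester[i], testers$ids)]],
                  map)
    dosage[i, ] <- lg + tg
  }
  list(dosage = dosage, design = design)
}

#' Concatenate populations that share a map
#'
#' @param ... \code{bc_population} objects with identical maps.
#' @return a single \code{bc_population}.
#' @export
bind_populations <- function(...) {
  pops <- list(...)
  stopifnot(length(pops) >= 1)
  map <- pops[[1]]$map
  for (p in pops[-1])
    if (!identical(p$map$marker, map$marker)) stop("populations share no map")
  structure(
    list(dosage = do.call(rbind, lapply(pops, `[[`, "dosage")),
         haplotypes = do.call(c, lapply(pops, `[[`, "haplotypes")),
         map = map,
         ids = do.call(c, lapply(pops, `[[`, "ids"))),
    class = "bc_population"
  )
}
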
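#' Simulate one meiosis
#'
#' Draws a single gamete from a diploid parent under a no-interference
#' (Poisson) crossover model.  Per chromosome the number of crossovers is
#' Poisson with mean equal to the chromosome's map length in Morgans,
#' crossover positions are uniform in centimorgans, and the starting haplotype
#' is chosen at random.  Two markers d Morgans apart therefore recombine with
#' Haldane's frequency 0.5 * (1 - exp(-2 d)).
#'
#' @param haplotypes 2 x m matrix of parental haplotypes (rows are the two
#'   homologs, columns follow the map order).
#' @param map genetic map data.frame (\code{marker}, \code{chrom},
#'   \code{pos_cM}) with one row per haplotype column.
#' @param seed optional seed; when NULL the ambient RNG stream is used so the
#'   caller controls reproducibility.
#' @return integer vector of length m: the gamete's allele at each marker.
#' @export
meiosis <- function(haplotypes, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.matrix(haplotypes) || nrow(haplotypes) != 2)
    stop("haplotypes must be a 2 x m matrix")
  if (ncol(haplotypes) != nrow(map))
    stop("haplotype length does not match map")
  validate_map(map)

  gamete <- integer(ncol(haplotypes))
  for (c in unique(map$chrom)) {
    idx <- which(map$chrom == c)
    pos <- map$pos_cM[idx]
    len_morgan <- (max(pos) - min(pos)) / 100
    n_co <- stats::rpois(1L, len_morgan)
    start <- sample.int(2L, 1L)
    if (n_co == 0L) {
      gamete[idx] <- haplotypes[start, idx]
      next
    }
    breaks <- sort(stats::runif(n_co, min(pos), max(pos)))
    # parity of crossovers to the left of each marker picks the homolog
    n_left <- findInterval(pos, breaks)
    hap <- (start - 1L + n_left) %% 2L + 1L
    gamete[idx] <- haplotypes[cbind(hap, idx)]
  }
  gamete
}

# Offspring genotype (2 x m) from two parents, one gamete each.
mate <- function(parent1, parent2, map) {
  rbind(meiosis(parent1, map), meiosis(parent2, map))
}

# Self-pollination: two independent gametes of the same plant.
self_plant <- function(plant, map) {
  rbind(meiosis(plant, map), meiosis(plant, map))
}
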
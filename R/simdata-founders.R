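#' Simulate a founder pair for a backcross introgression population
#'
#' Builds a fully homozygous recurrent (elite) parent and a fully homozygous
#' exotic (unadapted) donor parent on a shared genetic map.  Alleles are coded
#' 0/1 per haplotype, with 1 the exotic allele: the recurrent parent carries 0
#' everywhere, and the exotic parent carries 1 at exactly
#' \code{floor(divergence * n_markers)} marker positions chosen uniformly at
#' random.  Map positions are drawn uniformly along each chromosome and sorted,
#' so positions are non-decreasing within a chromosome.
#'
#' @param n_markers total number of biallelic markers.
#' @param n_chromosomes number of chromosomes; markers are split as evenly as
#'   possible across them (sorghum has 10).
#' @param divergence fraction of markers at which the two parents carry
#'   different alleles, in (0, 1].
#' @param chrom_length_cM genetic length of each chromosome in centimorgans.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   founders.
#'
#' @return an object of class \code{founder_pair}: a list with elements
#'   \code{recurrent} and \code{exotic} (2 x m haplotype matrices),
#'   \code{map} (data.frame with \code{marker}, \code{chrom}, \code{pos_cM}),
#'   and \code{divergence}.
#' @export
simulate_founders <- function(n_markers, n_chromosomes = 10, divergence,
                              chrom_length_cM = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_markers < 1 || n_chromosomes < 1 || n_markers < n_chromosomes)
    stop("need n_markers >= n_chromosomes >= 1")
  if (divergence <= 0 || divergence > 1)
    stop("divergence must be in (0, 1]")
  if (chrom_length_cM <= 0) stop("chrom_length_cM must be positive")

  chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- numeric(n_markers)
  for (c in seq_len(n_chromosomes)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(stats::runif(length(idx), 0, chrom_length_cM))
  }
  map <- data.frame(
    marker = sprintf("M%05d", seq_len(n_markers)),
    chrom = chrom,
    pos_cM = pos,
    stringsAsFactors = FALSE
  )

  n_div <- floor(divergence * n_markers)
  div_idx <- sort(sample.int(n_markers, n_div))
  exotic_allele <- integer(n_markers)
  exotic_allele[div_idx] <- 1L

  recurrent <- matrix(0L, nrow = 2, ncol = n_markers,
                      dimnames = list(NULL, map$marker))
  exotic <- matrix(rep(exotic_allele, each = 2), nrow = 2,
                   dimnames = list(NULL, map$marker))

  structure(
    list(recurrent = recurrent, exotic = exotic, map = map,
         divergence = divergence),
    class = "founder_pair"
  )
}

#' Markers at which the two founders differ
#'
#' @param founders a \code{founder_pair}.
#' @return integer vector of column indices of divergent markers.
#' @export
divergent_markers <- function(founders) {
  which(founders$recurrent[1, ] != founders$exotic[1, ])
}

validate_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker", "chrom", "pos_cM") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicate marker ids in map")
  if (any(map$pos_cM < 0)) stop("negative map positions")
  ok <- tapply(map$pos_cM, map$chrom, function(p) !is.unsorted(p))
  if (!all(ok)) stop("map positions must be non-decreasing within chromosome")
  invisible(map)
}
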
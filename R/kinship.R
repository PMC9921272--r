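#' Allele frequencies of a dosage matrix
#'
#' @param markers individuals x markers dosage matrix (entries 0/1/2, the
#'   count of the alternate allele).
#' @return numeric vector of alternate-allele frequencies per marker.
#' @export
allele_freq <- function(markers) {
  check_dosage(markers)
  colMeans(markers) / 2
}

check_dosage <- function(markers) {
  if (!is.matrix(markers)) stop("dosage must be a matrix")
  if (anyNA(markers)) stop("missing dosage entries; impute upstream")
  if (!all(markers %in% c(0, 1, 2))) stop("dosage entries must be 0, 1 or 2")
  invisible(markers)
}

#' Minor-allele-frequency filter
#'
#' Removes markers whose minor allele frequency is strictly below the
#' threshold (a marker at exactly the threshold is retained); marker order is
#' preserved.
#'
#' @param markers dosage matrix.
#' @param threshold MAF threshold in [0, 0.5] (default 0.05).
#' @return the filtered dosage matrix, with attribute \code{n_removed}.
#' @export
maf_filter <- function(markers, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  p <- allele_freq(markers)
  keep <- pmin(p, 1 - p) >= threshold
  if (!any(keep)) stop("all markers removed by MAF filter")
  out <- markers[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' K = X X' / (2 * sum p_i (1 - p_i)) with X the dosage matrix column-centred
#' by twice the alternate-allele frequency; frequencies are estimated from
#' the panel being processed.
#'
#' @param markers dosage matrix (individuals x markers).
#' @return symmetric relationship matrix with the individuals' ids, class
#'   \code{grm_kernel}, attribute \code{kind = "additive"} and the scaling
#'   denominator in attribute \code{denominator}.
#' @export
additive_grm <- function(markers) {
  p <- allele_freq(markers)
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all markers monomorphic: zero GRM denominator")
  X <- sweep(markers, 2, 2 * p)
  K <- tcrossprod(X) / denom
  structure(K, kind = "additive", denominator = denom, class = "grm_kernel")
}

#' Dominance genomic relationship matrix (Vitezica orthogonal coding)
#'
#' Per marker with alternate-allele frequency p (q = 1 - p) the dominance
#' covariate is -2q^2 for dosage 2, 2pq for dosage 1 and -2p^2 for dosage 0;
#' K_D = W W' / sum (2 p q)^2.  Under Hardy-Weinberg this coding is
#' orthogonal to the additive one.
#'
#' @param markers dosage matrix.
#' @return dominance kernel, class \code{grm_kernel}, kind "dominance".
#' @export
dominance_grm <- function(markers) {
  p <- allele_freq(markers)
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  if (denom == 0) stop("no polymorphic markers: zero dominance denominator")
  n <- nrow(markers)
  W <- matrix(0, n, ncol(markers), dimnames = dimnames(markers))
  for (g in 0:2) {
    cov_g <- switch(as.character(g),
                    "0" = -2 * p^2, "1" = 2 * p * q, "2" = -2 * q^2)
    idx <- markers == g
    W[idx] <- matrix(rep(cov_g, each = n), n)[idx]
  }
  K <- tcrossprod(W) / denom
  structure(K, kind = "dominance", denominator = denom, class = "grm_kernel")
}

#' Hybrid relationship kernel from parental kernels
#'
#' The full line-by-tester covariance is the Kronecker product
#' K_tester %x% K_line; rows and columns are then extracted for the realized
#' hybrids only, so the entry for hybrids (l1, t1) and (l2, t2) is
#' K_tester[t1, t2] * K_line[l1, l2].
#'
#' @param line_kernel,tester_kernel parental kernels of the same kind
#'   (additive or dominance), with dimnames giving parent ids.
#' @param design data.frame with columns \code{hybrid}, \code{line},
#'   \code{tester}.
#' @return hybrid x hybrid kernel, class \code{grm_kernel}.
#' @export
hybrid_kernel <- function(line_kernel, tester_kernel, design) {
  kind_l <- attr(line_kernel, "kind"); kind_t <- attr(tester_kernel, "kind")
  if (!is.null(kind_l) && !is.null(kind_t) && !identical(kind_l, kind_t))
    stop("parental kernels are of different kinds")
  stopifnot(all(c("hybrid", "line", "tester") %in% names(design)))
  li <- match(design$line, rownames(line_kernel))
  ti <- match(design$tester, rownames(tester_kernel))
  if (anyNA(li)) stop("hybrid references unknown line")
  if (anyNA(ti)) stop("hybrid references unknown tester")
  K <- unclass(tester_kernel)[ti, ti, drop = FALSE] *
    unclass(line_kernel)[li, li, drop = FALSE]
  dimnames(K) <- list(design$hybrid, design$hybrid)
  structure(K, kind = kind_l, class = "grm_kernel")
}

#' Identity-by-state genetic distance
#'
#' d(i, j) = 1 - mean over markers of the IBS allele share, where the share
#' at one marker is (2 - |dosage_i - dosage_j|) / 2, i.e. 1 for identical
#' genotypes, 0.5 for het vs hom, 0 for opposite homozygotes.
#'
#' @param markers dosage matrix.
#' @return symmetric distance matrix in [0, 1] with zero diagonal.
#' @export
ibs_distance <- function(markers) {
  check_dosage(markers)
  if (ncol(markers) == 0) stop("zero markers")
  n <- nrow(markers)
  D <- matrix(0, n, n, dimnames = list(rownames(markers), rownames(markers)))
  for (i in seq_len(n)) {
    diffs <- abs(sweep(markers, 2, markers[i, ]))
    D[i, ] <- rowMeans(diffs) / 2
  }
  D
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: double-centre -0.5 * D^2, eigendecompose, scale
#' eigenvectors by the square root of their (positive) eigenvalues.  Axes
#' with non-positive eigenvalues are dropped and excluded from the
#' percent-variance base.
#'
#' @param distance symmetric distance matrix (n >= 3).
#' @return list of class \code{pcoa_result}: \code{coordinates} (n x k),
#'   \code{eigenvalues} (positive, decreasing), \code{percent} variance per
#'   axis.
#' @export
pcoa <- function(distance) {
  n <- nrow(distance)
  if (n < 3) stop("PCoA needs at least 3 entities")
  if (max(abs(distance - t(distance))) > 1e-8) stop("distance not symmetric")
  # cmdscale warns when the configuration needs fewer than k axes; expected
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(distance), k = n - 1, eig = TRUE))
  pos <- sc$eig > 1e-12 * max(abs(sc$eig))
  eig <- sc$eig[pos]
  coords <- sc$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig,
                 percent = 100 * eig / sum(eig)),
            class = "pcoa_result")
}

#' Regression of hybrid performance on line genetic distance
#'
#' Ordinary least squares of a hybrid trait BLUE on the line's genetic
#' distance from its introgression (donor) parent, the screen used to ask
#' whether recovered-genome fraction predicts testcross performance.
#'
#' @param distance numeric vector: line distance to the donor parent.
#' @param blue numeric vector: matching hybrid BLUEs.
#' @return list: slope, intercept, r (Pearson), r_squared, p_slope, n.
#' @export
distance_yield_regression <- function(distance, blue) {
  stopifnot(length(distance) == length(blue))
  ok <- is.finite(distance) & is.finite(blue)
  distance <- distance[ok]; blue <- blue[ok]
  if (length(distance) < 3) stop("need >= 3 paired observations")
  if (stats::var(distance) == 0) stop("zero variance in distances")
  fit <- stats::lm(blue ~ distance)
  s <- summary(fit)
  r <- stats::cor(distance, blue)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = unname(s$r.squared),
       p_slope = unname(s$coefficients[2, 4]),
       n = length(distance))
}

#' Verify a kernel is symmetric positive semi-definite up to jitter
#'
#' @param K kernel matrix.
#' @param tol relative eigenvalue tolerance.
#' @return TRUE invisibly; errors otherwise.
#' @export
check_kernel_psd <- function(K, tol = 1e-8) {
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    stop("kernel not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev))) stop("kernel not PSD within tolerance")
  invisible(TRUE)
}
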
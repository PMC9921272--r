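#' Load a genotype matrix from VCF or TSV
#'
#' VCF input (parsed with vcfR) keeps biallelic SNP records only; the GT
#' field is converted to the alternate-allele dosage.  Multi-allelic records
#' are skipped and their count reported in attribute \code{n_multiallelic}.
#' Missing genotypes ("./." or ".") trigger the missing-data policy: fail
#' (default) or mean-impute (rounded to the nearest dosage class).
#' TSV input expects individuals in rows (first column = id) and marker ids
#' in the header; cells must be 0/1/2.
#'
#' @param path file path.
#' @param format "vcf" or "tsv"; guessed from the extension when NULL.
#' @param missing "fail" or "mean_impute".
#' @return individuals x markers integer dosage matrix with ids as dimnames;
#'   attributes \code{n_multiallelic} and \code{n_imputed} for VCF input.
#' @export
load_genotypes <- function(path, format = NULL, missing = c("fail", "mean_impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"

  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids)) stop("duplicate individual ids in ", path)
    m <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(!(m %in% c(0, 1, 2)) | is.na(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(m))
      stop("non-{0,1,2} dosage at row ", ids[rc[1]], ", marker ",
           colnames(m)[rc[2]])
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    return(m)
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  n_multi <- sum(multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  marker_ids <- fix[!multi, "ID"]
  no_id <- is.na(marker_ids) | marker_ids == "."
  marker_ids[no_id] <- paste0(fix[!multi, "CHROM"], "_",
                              fix[!multi, "POS"])[no_id]
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids in ", path)
  if (anyDuplicated(colnames(gt))) stop("duplicate individual ids in ", path)

  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  n_imp <- 0L
  if (anyNA(dos)) {
    if (missing == "fail")
      stop("missing genotypes in ", path, "; use missing = 'mean_impute'")
    for (j in which(apply(dos, 1, anyNA))) {
      mu <- mean(dos[j, ], na.rm = TRUE)
      na_idx <- is.na(dos[j, ])
      n_imp <- n_imp + sum(na_idx)
      dos[j, na_idx] <- as.integer(pmin(2, pmax(0, round(mu))))
    }
  }
  out <- t(dos)
  dimnames(out) <- list(colnames(gt), marker_ids)
  storage.mode(out) <- "integer"
  attr(out, "n_multiallelic") <- n_multi
  attr(out, "n_imputed") <- n_imp
  out
}

#' Write a dosage matrix as an (unphased) VCF
#'
#' Dosages 0/1/2 become GT 0/0, 0/1 and 1/1 with placeholder REF/ALT
#' alleles; marker positions come from the map when supplied, otherwise
#' markers are laid on one contig at consecutive positions.
#'
#' @param markers individuals x markers dosage matrix.
#' @param path output path (plain-text .vcf).
#' @param map optional data.frame (marker, chrom, pos_cM) aligned to columns.
#' @export
write_genotypes_vcf <- function(markers, path, map = NULL) {
  check_dosage(markers)
  ids <- rownames(markers)
  mk <- colnames(markers)
  if (is.null(map)) {
    chrom <- rep(1L, ncol(markers)); pos <- seq_len(ncol(markers))
  } else {
    stopifnot(identical(map$marker, mk))
    chrom <- map$chrom
    # cM positions mapped to distinct integer bp coordinates per chromosome
    pos <- stats::ave(map$pos_cM, map$chrom,
                      FUN = function(p) rank(p, ties.method = "first"))
  }
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=bcnamScreen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(markers)), function(j) {
    paste(c(chrom[j], pos[j], mk[j], "A", "T", ".", "PASS", ".", "GT",
            gt_code[markers[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a dosage matrix as TSV
#'
#' @param markers dosage matrix.
#' @param path output path.
#' @export
write_genotypes_tsv <- function(markers, path) {
  check_dosage(markers)
  df <- data.frame(id = rownames(markers), markers, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype CSV
#'
#' Expects the columns written by the simulator (hybrid, line, tester,
#' population, environment, replicate, trait, value); a \code{column_map}
#' (new_name = old_name) adapts other layouts.
#'
#' @param path CSV path.
#' @param column_map optional named character vector renaming columns.
#' @return plot-level data.frame.
#' @export
read_phenotypes <- function(path, column_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(d))
        stop("column_map refers to absent column ", column_map[[nm]])
      names(d)[names(d) == column_map[[nm]]] <- nm
    }
  need <- c("hybrid", "environment", "replicate", "trait", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("phenotype file lacks columns: ",
                         paste(miss, collapse = ", "))
  key <- do.call(paste, d[, c("hybrid", "environment", "replicate", "trait")])
  if (anyDuplicated(key)) stop("duplicate plot records")
  if (any(!is.finite(d$value))) stop("non-finite phenotype values")
  d
}

#' Write a kernel or distance matrix as TSV with an id header
#' @param K square matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kernel or distance matrix written by \code{write_matrix_tsv}
#' @param path TSV path.
#' @return square numeric matrix with ids as dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
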
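#' Genotype matrix container
#'
#' Bundles a biallelic SNP dosage matrix (individuals in rows, markers in
#' columns, codes -1/0/1 for the three genotype classes, `NA` for missing
#' calls) with a marker map giving chromosome and 1-based physical position.
#'
#' @param dosage numeric matrix, individuals x markers; values must be in
#'   \{-1, 0, 1, NA\}. Row names are sample ids, column names marker ids
#'   (generated when absent).
#' @param map data.frame with columns `marker`, `chrom`, `pos` (1-based).
#'   When `NULL`, all markers are placed on one chromosome at consecutive
#'   positions. Markers must be sorted by (chrom, pos).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `map`.
#' @export
genotype_matrix <- function(dosage, map = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  ok <- dosage %in% c(-1, 0, 1) | is.na(dosage)
  if (!all(ok))
    stop("dosage codes must be -1, 0, 1 or NA")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind_%d", seq_len(nrow(dosage)))
  if (anyDuplicated(rownames(dosage)))
    stop("duplicate sample ids in dosage matrix")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp_%d", seq_len(ncol(dosage)))
  if (is.null(map)) {
    map <- data.frame(marker = colnames(dosage),
                      chrom = "1",
                      pos = seq_len(ncol(dosage)),
                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(dosage))
  map$chrom <- as.character(map$chrom)
  # numeric-like chromosome names sort naturally (1, 2, ..., 10), others
  # lexicographically
  chrom_key <- suppressWarnings(as.numeric(map$chrom))
  ord <- if (anyNA(chrom_key)) order(map$chrom, map$pos)
         else order(chrom_key, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
  }
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$dosage)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%d chromosome%s, %.1f%% missing)\n",
              d[1], d[2], length(unique(x$map$chrom)),
              if (length(unique(x$map$chrom)) == 1) "" else "s", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x genotype_matrix
#' @param i individual index (ids or positions)
#' @param j marker index (ids or positions)
#' @param ... unused
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  d <- x$dosage[i, j, drop = FALSE]
  if (is.character(j)) j <- match(j, x$map$marker)
  if (is.logical(j)) j <- which(j)
  genotype_matrix(d, x$map[j, , drop = FALSE])
}

sample_ids <- function(geno) rownames(geno$dosage)

#' Allele frequencies from dosages
#'
#' Frequency of the allele coded +1, computed as `(mean(dosage) + 1) / 2`
#' per marker, ignoring missing calls.
#'
#' @param geno genotype_matrix
#' @return numeric vector, one frequency per marker
#' @export
allele_freq <- function(geno) {
  (colMeans(geno$dosage, na.rm = TRUE) + 1) / 2
}
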
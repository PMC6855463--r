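#' Filter markers on call rate
#'
#' Removes markers whose fraction of non-missing calls falls below
#' `min_rate` (default 90%, the usual GBS quality-control threshold).
#'
#' @param geno genotype_matrix
#' @param min_rate minimum fraction of individuals with an observed call,
#'   in (0, 1]
#' @return genotype_matrix with failing markers removed; attributes
#'   `n_removed` and `n_retained` report the counts.
#' @export
filter_call_rate <- function(geno, min_rate = 0.90) {
  stopifnot(min_rate > 0, min_rate <= 1)
  rate <- colMeans(!is.na(geno$dosage))
  keep <- rate >= min_rate
  if (!any(keep))
    warning("no markers pass the call-rate filter")
  out <- geno[, keep]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Naive per-marker imputation
#'
#' Replaces each missing call by the modal dosage of its marker; ties are
#' resolved to the heterozygote code 0. A deliberately simple stand-in for
#' haplotype-based imputation: downstream genomic prediction only needs a
#' complete dosage matrix.
#'
#' @param geno genotype_matrix, call-rate filtered
#' @return genotype_matrix without missing values
#' @export
impute_naive <- function(geno) {
  d <- geno$dosage
  nmiss <- colSums(is.na(d))
  if (any(nmiss == nrow(d)))
    stop("marker(s) with zero observed calls; apply filter_call_rate() first: ",
         paste(utils::head(geno$map$marker[nmiss == nrow(d)], 5), collapse = ", "))
  for (j in which(nmiss > 0)) {
    cnt <- tabulate(d[, j] + 2, nbins = 3)   # counts of -1, 0, 1
    mode_dos <- if (sum(cnt == max(cnt)) > 1) 0 else c(-1, 0, 1)[which.max(cnt)]
    d[is.na(d[, j]), j] <- mode_dos
  }
  genotype_matrix(d, geno$map)
}

#' Filter markers on minor allele frequency
#'
#' Markers with minor allele frequency strictly below `min_maf` are
#' removed; the boundary is inclusive (a marker at exactly `min_maf` is
#' kept).
#'
#' @param geno genotype_matrix with no missing values
#' @param min_maf minimum minor allele frequency (default 0.05)
#' @return filtered genotype_matrix with `n_removed`/`n_retained` attributes
#' @export
filter_maf <- function(geno, min_maf = 0.05) {
  if (anyNA(geno$dosage))
    stop("filter_maf() requires a complete matrix; impute first")
  p <- allele_freq(geno)
  maf <- pmin(p, 1 - p)
  keep <- maf >= min_maf - 1e-12
  out <- geno[, keep]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Run the standard marker QC pipeline
#'
#' Call-rate filter, then naive imputation, then MAF filter, in that order.
#'
#' @param geno genotype_matrix
#' @param min_call_rate call-rate threshold (default 0.90)
#' @param min_maf MAF threshold (default 0.05)
#' @return complete, filtered genotype_matrix; attribute `qc_report` holds
#'   the per-step retained/removed counts.
#' @export
qc_genotypes <- function(geno, min_call_rate = 0.90, min_maf = 0.05) {
  g1 <- filter_call_rate(geno, min_call_rate)
  g2 <- impute_naive(g1)
  g3 <- filter_maf(g2, min_maf)
  attr(g3, "qc_report") <- list(
    n_input = ncol(geno$dosage),
    call_rate = list(threshold = min_call_rate,
                     removed = attr(g1, "n_removed"),
                     retained = attr(g1, "n_retained")),
    maf = list(threshold = min_maf,
               removed = attr(g3, "n_removed"),
               retained = attr(g3, "n_retained")))
  g3
}

centered_dosage <- function(geno) {
  Z <- geno$dosage
  if (anyNA(Z)) stop("kernel construction requires a complete dosage matrix")
  p <- (colMeans(Z) + 1) / 2
  # VanRaden centering: subtract 2(p - 0.5) = column mean
  list(Zc = sweep(Z, 2, 2 * (p - 0.5)), p = p)
}

#' Additive genomic relationship matrix
#'
#' VanRaden's G: columns of the dosage matrix are centered by twice the
#' allele-frequency deviation from 0.5 and the cross-product is scaled by
#' `2 * sum(p * (1 - p))`, so the expected diagonal is ~1 under
#' Hardy-Weinberg. The uncentered cross-product (the literal `ZZ'` form)
#' is available with `center = FALSE`. A small ridge is added to the
#' diagonal so the matrix is safely invertible.
#'
#' @param geno complete genotype_matrix (after QC)
#' @param center center dosage columns before the cross-product (default TRUE)
#' @param ridge diagonal stabiliser (default 1e-6)
#' @return `kinship_matrix` of kind `"additive_G"`. The scaling constant
#'   `2 * sum(p*(1-p))` is stored in the provenance as `denom`.
#' @export
additive_G <- function(geno, center = TRUE, ridge = 1e-6) {
  cd <- centered_dosage(geno)
  denom <- 2 * sum(cd$p * (1 - cd$p))
  if (denom <= 0)
    stop("all markers are monomorphic; cannot scale G")
  Z <- if (center) cd$Zc else geno$dosage
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridge
  kinship_matrix(G, kind = "additive_G",
                 provenance = list(n_markers = ncol(geno$dosage),
                                   denom = denom, centered = center,
                                   ridge = ridge))
}

#' Gaussian kernel matrix
#'
#' `K = exp(-h * D / median(D))` where `D` holds squared Euclidean
#' distances between individuals' dosage rows and the median is taken over
#' the off-diagonal entries (the bandwidth convention of RKHS genomic
#' prediction). `h` is the bandwidth reduction coefficient, 1 by default.
#' Plain (unsquared) Euclidean distances can be requested with
#' `distance = "euclidean"`.
#'
#' @param geno complete genotype_matrix (after QC)
#' @param h bandwidth reduction coefficient (default 1)
#' @param distance "squared" (default) or "euclidean"
#' @return `kinship_matrix` of kind `"gaussian_K"` with unit diagonal.
#' @export
gaussian_K <- function(geno, h = 1, distance = c("squared", "euclidean")) {
  distance <- match.arg(distance)
  Z <- geno$dosage
  if (anyNA(Z)) stop("kernel construction requires a complete dosage matrix")
  D <- as.matrix(stats::dist(Z))^2
  if (distance == "euclidean") D <- sqrt(D)
  med <- stats::median(D[upper.tri(D)])
  if (!is.finite(med) || med <= 0)
    stop("median marker distance is zero; individuals are all identical")
  K <- exp(-h * D / med)
  K <- (K + t(K)) / 2
  kinship_matrix(K, kind = "gaussian_K",
                 provenance = list(n_markers = ncol(Z), h = h,
                                   distance = distance, median_D = med))
}

#' Kinship matrix container
#'
#' @param mat symmetric numeric matrix with sample ids as dimnames
#' @param kind "additive_G" or "gaussian_K"
#' @param provenance list of construction metadata
#' @return matrix with class `kinship_matrix` and attributes `kind`,
#'   `provenance`
#' @export
kinship_matrix <- function(mat, kind = c("additive_G", "gaussian_K"),
                           provenance = list()) {
  kind <- match.arg(kind)
  if (max(abs(mat - t(mat))) > 1e-10) stop("kinship matrix must be symmetric")
  structure(mat, class = c("kinship_matrix", "matrix"),
            kind = kind, provenance = provenance)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s): %d individuals, mean diagonal %.3f\n",
              attr(x, "kind"), nrow(x), mean(diag(x))))
  invisible(x)
}

#' Pairwise linkage disequilibrium (r^2) within a chromosome
#'
#' Squared Pearson correlation between dosage vectors for every marker
#' pair on one chromosome, with the inter-marker distance in base pairs.
#' Monomorphic (zero-variance) markers are skipped with a warning.
#'
#' @param geno complete genotype_matrix
#' @param chromosome chromosome id (must match the map)
#' @return data.frame with columns `marker_a`, `marker_b`, `dist_bp`, `r2`
#' @export
ld_r2 <- function(geno, chromosome) {
  idx <- which(geno$map$chrom == as.character(chromosome))
  if (length(idx) < 2)
    stop("need at least two markers on chromosome ", chromosome)
  Z <- geno$dosage[, idx, drop = FALSE]
  v <- apply(Z, 2, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance marker(s) skipped in LD computation")
    idx <- idx[v > 0]
    Z <- Z[, v > 0, drop = FALSE]
  }
  r2 <- stats::cor(Z)^2
  pos <- geno$map$pos[idx]
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  data.frame(marker_a = geno$map$marker[idx][ut[, 1]],
             marker_b = geno$map$marker[idx][ut[, 2]],
             dist_bp = abs(pos[ut[, 2]] - pos[ut[, 1]]),
             r2 = r2[ut],
             stringsAsFactors = FALSE)
}

#' Heterozygosity summaries
#'
#' @param geno genotype_matrix (heterozygote coded 0); missing calls are
#'   ignored in the denominators
#' @return list with `individual` (per-individual multilocus
#'   heterozygosity) and `marker` (per-marker observed heterozygosity Ho)
#' @export
heterozygosity <- function(geno) {
  het <- geno$dosage == 0
  list(individual = rowMeans(het, na.rm = TRUE),
       marker = colMeans(het, na.rm = TRUE))
}
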
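#' Discriminant analysis of principal components (DAPC)
#'
#' Infers population structure in three steps: (1) PCA of the centered
#' dosage matrix (or eigendecomposition of a supplied kinship matrix),
#' keeping the leading axes that explain at least `pc_variance_threshold`
#' of total variance; (2) k-means on the retained PCs, either at a fixed
#' `k` or choosing `k` over 2..10 by minimum BIC; (3) linear discriminant
#' analysis of the k-means labels on the retained PCs. Final labels are
#' nearest-centroid assignments in the retained discriminant space (ties
#' go to the lowest cluster index).
#'
#' @param x `genotype_matrix` (complete) or `kinship_matrix`
#' @param k number of clusters, or `"auto"` for BIC selection over 2..10
#' @param pc_variance_threshold cumulative variance the retained PCs must
#'   reach (default 0.85)
#' @param df_variance_threshold cumulative share of discriminant variance
#'   the retained discriminant functions must reach (default 0.94)
#' @param seed integer seed for the k-means restarts
#' @param k_max largest k tried when `k = "auto"`
#' @return object of class `dapc_model` with elements `labels` (final
#'   cluster per individual), `kmeans_labels`, `k`, `pc_scores`,
#'   `pc_variance` (per-axis share), `n_pcs`, `bic` (data.frame over k, or
#'   NULL when k fixed), `discriminant` (scores, coefficients, per-function
#'   variance share, number retained), `centroids`
#' @export
dapc_fit <- function(x, k = "auto", pc_variance_threshold = 0.85,
                     df_variance_threshold = 0.94, seed = 1L, k_max = 10) {
  stopifnot(pc_variance_threshold > 0, pc_variance_threshold <= 1,
            df_variance_threshold > 0, df_variance_threshold <= 1)
  if (inherits(x, "genotype_matrix")) {
    Z <- x$dosage
    if (anyNA(Z)) stop("dapc_fit() needs complete dosages; run QC first")
    Zc <- sweep(Z, 2, colMeans(Z))
    sv <- svd(Zc, nu = min(dim(Zc)) - 1, nv = 0)
    ev <- sv$d[seq_len(min(dim(Zc)) - 1)]^2
    scores <- sv$u %*% diag(sv$d[seq_along(ev)], length(ev))
    rownames(scores) <- rownames(Z)
  } else if (inherits(x, "kinship_matrix") || (is.matrix(x) && isSymmetric(unclass(x)))) {
    eg <- eigen(unclass(x), symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-9
    ev <- eg$values[pos]
    scores <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev), length(ev))
    rownames(scores) <- rownames(x)
  } else stop("x must be a genotype_matrix or a kinship (symmetric) matrix")

  n <- nrow(scores)
  share <- ev / sum(ev)
  n_pcs <- which(cumsum(share) >= pc_variance_threshold - 1e-12)[1]
  n_pcs <- max(n_pcs, 1)
  S <- scores[, seq_len(n_pcs), drop = FALSE]

  bic_tab <- NULL
  kmeans_bic <- function(km) {
    # conventional DAPC criterion: n log(WSS/n) + k log(n)
    n * log(km$tot.withinss / n) + length(km$size) * log(n)
  }
  run_kmeans <- function(kk, sd_offset = 0) {
    for (try in 0:10) {
      set.seed(as.integer(seed) + 97L * try + sd_offset)
      km <- suppressWarnings(stats::kmeans(S, centers = kk, nstart = 25,
                                           iter.max = 100))
      if (all(km$size > 0)) return(km)
    }
    stop("k-means produced an empty cluster for k = ", kk,
         " despite re-seeded retries")
  }

  if (identical(k, "auto")) {
    kk_grid <- 2:min(k_max, n - 1)
    fits <- lapply(kk_grid, function(kk) run_kmeans(kk, sd_offset = kk))
    bics <- vapply(fits, kmeans_bic, 0)
    bic_tab <- data.frame(k = kk_grid, bic = bics)
    km <- fits[[which.min(bics)]]
    k <- kk_grid[which.min(bics)]
  } else {
    k <- as.integer(k)
    if (k > n - 1) stop("k must be at most n - 1 = ", n - 1)
    if (k == 1) {
      labels <- stats::setNames(rep(1L, n), rownames(scores))
      return(structure(list(labels = labels, kmeans_labels = labels, k = 1L,
                            pc_scores = S, pc_variance = share, n_pcs = n_pcs,
                            bic = NULL, discriminant = NULL,
                            centroids = NULL),
                       class = "dapc_model"))
    }
    km <- run_kmeans(k)
  }

  km_labels <- stats::setNames(km$cluster, rownames(scores))
  ld <- MASS::lda(S, grouping = factor(km_labels))
  df_scores <- S %*% ld$scaling
  df_share <- ld$svd^2 / sum(ld$svd^2)
  n_df <- which(cumsum(df_share) >= df_variance_threshold - 1e-12)[1]
  DS <- df_scores[, seq_len(n_df), drop = FALSE]
  centroids <- apply(DS, 2, function(col) tapply(col, km_labels, mean))
  centroids <- matrix(centroids, nrow = k,
                      dimnames = list(sort(unique(km_labels)), colnames(DS)))
  d2 <- outer(rowSums(DS^2), rowSums(centroids^2), "+") - 2 * DS %*% t(centroids)
  labels <- stats::setNames(as.integer(apply(d2, 1, which.min)),  # ties -> lowest index
                            rownames(scores))

  structure(list(labels = labels, kmeans_labels = km_labels, k = as.integer(k),
                 pc_scores = S, pc_variance = share, n_pcs = n_pcs,
                 bic = bic_tab,
                 discriminant = list(scores = df_scores,
                                     coefficients = ld$scaling,
                                     variance_share = df_share,
                                     n_retained = n_df),
                 centroids = centroids),
            class = "dapc_model")
}

#' Cluster sizes of a DAPC model
#'
#' @param model `dapc_model`
#' @return named integer vector, one count per cluster (deterministic)
#' @export
cluster_sizes <- function(model) {
  stopifnot(inherits(model, "dapc_model"))
  tab <- table(factor(model$labels, levels = seq_len(model$k)))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d individuals, k = %d, %d PCs retained", length(x$labels), x$k, x$n_pcs))
  if (!is.null(x$discriminant))
    cat(sprintf(", %d discriminant function(s)", x$discriminant$n_retained))
  cat("\n  cluster sizes:", paste(cluster_sizes(x), collapse = " / "), "\n")
  invisible(x)
}

#' Best-permutation agreement between two labelings
#'
#' Fraction of individuals on which two cluster labelings agree after
#' optimally permuting the labels of the second (greedy matching on the
#' confusion matrix; exact for well-separated clusterings).
#'
#' @param a,b integer label vectors of equal length
#' @return agreement fraction in \[0, 1\]
#' @export
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  agree <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[ij[1], ij[2]]
    tab <- tab[-ij[1], -ij[2], drop = FALSE]
  }
  agree / length(a)
}
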
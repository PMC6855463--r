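#' Build a cross-validation plan
#'
#' Four population-structure-aware designs:
#'
#' * `"S1_random"` — random k-fold CV of all clones, ignoring structure
#'   (default 5 folds x 3 replicates); per replicate the validation folds
#'   partition the panel.
#' * `"S2_within_cluster"` — folds drawn within each cluster; training and
#'   validation come from the same cluster (default 3 folds x 3 reps).
#' * `"S3_leave_cluster_out"` — validation is a fold-part of one cluster;
#'   training is the matching fold-part of every *other* cluster (or the
#'   full other clusters with `full_training = TRUE`).
#' * `"S4_three_cluster_training"` — as S3 but the training set
#'   additionally drops one further cluster; every choice of absent
#'   cluster is enumerated.
#'
#' The plan is seed-locked: every prediction method served from the same
#' plan sees identical training/validation index sets.
#'
#' @param strategy one of the four strategy codes (unambiguous prefixes
#'   "s1".."s4" also accepted)
#' @param ids character vector of clone ids
#' @param cluster_labels named integer vector (required for S2-S4; S4
#'   needs >= 3 clusters)
#' @param folds folds per unit (default 5 for S1, 3 otherwise)
#' @param replicates independent re-randomisations (default 3)
#' @param seed integer seed
#' @param full_training S3 only: train on the complete other clusters
#'   instead of matching fold-parts
#' @return object of class `cv_plan`: list with `strategy`, `folds`,
#'   `replicates`, `seed` and `entries`, a list of records each holding
#'   `replicate`, `fold`, `validation_cluster`, `absent_cluster`,
#'   `train_ids`, `validation_ids`
#' @export
make_cv_plan <- function(strategy = c("S1_random", "S2_within_cluster",
                                      "S3_leave_cluster_out",
                                      "S4_three_cluster_training"),
                         ids, cluster_labels = NULL,
                         folds = NULL, replicates = 3, seed = 1L,
                         full_training = FALSE) {
  if (is.character(strategy) && length(strategy) == 1 &&
      tolower(strategy) %in% c("s1", "s2", "s3", "s4"))
    strategy <- c("S1_random", "S2_within_cluster", "S3_leave_cluster_out",
                  "S4_three_cluster_training")[match(tolower(strategy),
                                                     c("s1", "s2", "s3", "s4"))]
  strategy <- match.arg(strategy)
  if (is.null(folds)) folds <- if (strategy == "S1_random") 5 else 3
  stopifnot(folds >= 2, replicates >= 1, length(ids) >= folds)
  if (strategy != "S1_random") {
    if (is.null(cluster_labels)) stop(strategy, " requires cluster labels")
    cluster_labels <- cluster_labels[ids]
    if (anyNA(cluster_labels)) stop("cluster labels missing for some ids")
    k <- length(unique(cluster_labels))
    if (k < 2) stop(strategy, " requires at least 2 clusters")
    if (strategy == "S4_three_cluster_training" && k < 3)
      stop("S4 requires at least 3 clusters")
    if (min(table(cluster_labels)) < folds)
      stop("folds exceed the smallest cluster size (",
           min(table(cluster_labels)), ")")
  }
  set.seed(as.integer(seed))
  assign_folds <- function(v) {
    # random fold labels, sizes as equal as possible
    sample(rep_len(seq_len(folds), length(v)))
  }
  entries <- list()
  for (rep_i in seq_len(replicates)) {
    if (strategy == "S1_random") {
      f <- assign_folds(ids)
      for (fold_i in seq_len(folds)) {
        entries[[length(entries) + 1L]] <- list(
          replicate = rep_i, fold = fold_i,
          validation_cluster = NA_integer_, absent_cluster = NA_integer_,
          train_ids = ids[f != fold_i], validation_ids = ids[f == fold_i])
      }
    } else {
      clus <- sort(unique(cluster_labels))
      f <- unlist(lapply(clus, function(cl) {
        v <- ids[cluster_labels == cl]
        stats::setNames(assign_folds(v), v)
      }))
      f <- f[ids]
      for (cl in clus) {
        in_cl <- cluster_labels == cl
        for (fold_i in seq_len(folds)) {
          val <- ids[in_cl & f == fold_i]
          if (strategy == "S2_within_cluster") {
            entries[[length(entries) + 1L]] <- list(
              replicate = rep_i, fold = fold_i,
              validation_cluster = cl, absent_cluster = NA_integer_,
              train_ids = ids[in_cl & f != fold_i], validation_ids = val)
          } else if (strategy == "S3_leave_cluster_out") {
            tr <- if (full_training) ids[!in_cl]
                  else ids[!in_cl & f == fold_i]
            entries[[length(entries) + 1L]] <- list(
              replicate = rep_i, fold = fold_i,
              validation_cluster = cl, absent_cluster = NA_integer_,
              train_ids = tr, validation_ids = val)
          } else {
            for (absent in setdiff(clus, cl)) {
              keep <- !in_cl & cluster_labels != absent
              entries[[length(entries) + 1L]] <- list(
                replicate = rep_i, fold = fold_i,
                validation_cluster = cl, absent_cluster = absent,
                train_ids = ids[keep & f == fold_i], validation_ids = val)
            }
          }
        }
      }
    }
  }
  structure(list(strategy = strategy, folds = folds, replicates = replicates,
                 seed = as.integer(seed), full_training = full_training,
                 entries = entries),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan [%s]: %d folds x %d replicates, %d train/validation entries\n",
              x$strategy, x$folds, x$replicates, length(x$entries)))
  invisible(x)
}

#' Predictive ability
#'
#' Pearson correlation between validation GEBVs and validation BLUPs
#' (not deregressed BLUPs).
#'
#' @param gebv_val,blup_val numeric vectors of equal length >= 3
#' @return correlation, or `NA` with a warning when either vector has
#'   zero variance
#' @export
predictive_ability <- function(gebv_val, blup_val) {
  stopifnot(length(gebv_val) == length(blup_val), length(gebv_val) >= 3)
  if (stats::var(gebv_val) == 0 || stats::var(blup_val) == 0) {
    warning("zero variance in GEBVs or BLUPs; predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(gebv_val, blup_val)
}

#' Dispersion bias of GEBVs
#'
#' Default is the regression slope
#' `cov(GEBV_train, y_train) / var(GEBV_train)` of the training
#' deregressed BLUPs on the training GEBVs; b > 1 means marker effects
#' are underestimated. `denominator = "sd"` gives the literal
#' standard-deviation-denominator variant `cov / sd(GEBV)`.
#'
#' @param gebv_train,y_train_deregressed numeric vectors, length >= 3
#' @param denominator `"var"` (slope, default) or `"sd"`
#' @return slope, or `NA` with a warning when GEBVs have zero variance
#' @export
bias <- function(gebv_train, y_train_deregressed,
                 denominator = c("var", "sd")) {
  denominator <- match.arg(denominator)
  stopifnot(length(gebv_train) == length(y_train_deregressed),
            length(gebv_train) >= 3)
  if (stats::var(gebv_train) == 0) {
    warning("zero variance in training GEBVs; bias undefined")
    return(NA_real_)
  }
  cv <- stats::cov(gebv_train, y_train_deregressed)
  if (denominator == "var") cv / stats::var(gebv_train)
  else cv / stats::sd(gebv_train)
}

#' Prediction accuracy
#'
#' Predictive ability divided by the square root of the phenotypic trait
#' heritability.
#'
#' @param r_yy predictive ability
#' @param h2_phen phenotypic heritability in (0, 1]
#' @return accuracy
#' @export
accuracy <- function(r_yy, h2_phen) {
  if (any(h2_phen <= 0) || any(h2_phen > 1))
    stop("h2_phen must be in (0, 1]")
  r_yy / sqrt(h2_phen)
}

#' Run cross-validation for one prediction method
#'
#' For every plan entry, trains the method on the deregressed BLUPs of
#' the training ids (flagged low-reliability clones excluded), predicts
#' the validation ids, and computes per-fold predictive ability
#' (GEBV vs validation BLUPs), training-set bias, accuracy and genomic
#' heritability. Kernels are built once on the full panel and folds are
#' served by subsetting, so every method sees identical fold memberships.
#'
#' @param plan `cv_plan`
#' @param method one of `"gblup"`, `"rrblup"`, `"rkhs"`, `"bayesb"`,
#'   `"blasso"`
#' @param geno complete `genotype_matrix` covering all plan ids
#' @param estimates deregressed `clonal_estimates` (from
#'   [fit_clonal_lmm()] + [deregress()])
#' @param trait trait label copied to the output (defaults to the
#'   estimates' trait)
#' @param kernel optional precomputed `kinship_matrix` (saves rebuilding
#'   per method); must match the method's kind
#' @param h Gaussian bandwidth for rkhs when the kernel is built here
#' @param n_iter,burn_in,thin,seed MCMC settings for Bayesian methods
#' @return `cv_result`: data.frame with one row per plan entry
#'   (strategy, method, trait, replicate, fold, validation_cluster,
#'   absent_cluster, n_train, n_val, predictive_ability, bias, accuracy,
#'   h2_gen); folds with fewer than 3 usable validation clones get `NA`
#'   metrics with a warning
#' @export
run_cv <- function(plan, method, geno, estimates, trait = NULL,
                   kernel = NULL, h = 1,
                   n_iter = 1500, burn_in = 500, thin = 5, seed = 1L) {
  stopifnot(inherits(plan, "cv_plan"), inherits(estimates, "clonal_estimates"))
  method <- match.arg(method, c("gblup", "rrblup", "rkhs", "bayesb", "blasso"))
  if (is.null(trait)) trait <- estimates$trait
  cl <- estimates$clones
  if (all(is.na(cl$deregressed)))
    stop("estimates are not deregressed; call deregress() first")
  yd <- stats::setNames(cl$deregressed, cl$clone)
  yb <- stats::setNames(cl$blup, cl$clone)
  h2p <- phenotypic_heritability(estimates)

  kernel_method <- method %in% c("gblup", "rkhs")
  if (kernel_method && is.null(kernel))
    kernel <- if (method == "gblup") additive_G(geno) else gaussian_K(geno, h = h)

  rows <- lapply(seq_along(plan$entries), function(i) {
    en <- plan$entries[[i]]
    tr <- en$train_ids[!is.na(yd[en$train_ids])]
    va <- en$validation_ids[!is.na(yb[en$validation_ids])]
    base <- data.frame(strategy = plan$strategy, method = toupper(method),
                       trait = trait, replicate = en$replicate, fold = en$fold,
                       validation_cluster = en$validation_cluster,
                       absent_cluster = en$absent_cluster,
                       n_train = length(tr), n_val = length(va),
                       predictive_ability = NA_real_, bias = NA_real_,
                       accuracy = NA_real_, h2_gen = NA_real_,
                       stringsAsFactors = FALSE)
    if (length(va) < 3 || length(tr) < 3) {
      warning("fold with fewer than 3 usable clones; metrics set to NA")
      return(base)
    }
    fit <- if (kernel_method)
      gs_fit(yd[tr], kernel = kernel, method = method)
    else
      gs_fit(yd[tr], geno = geno[tr, ], method = method,
             n_iter = n_iter, burn_in = burn_in, thin = thin,
             seed = seed + 7L * i)
    gebv_val <- if (kernel_method) predict(fit, va) else predict(fit, geno[va, ])
    r <- suppressWarnings(predictive_ability(gebv_val, yb[va]))
    base$predictive_ability <- r
    base$bias <- suppressWarnings(bias(fit$g, yd[tr]))
    base$accuracy <- accuracy(r, h2p)
    base$h2_gen <- fit$h2_gen
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d fold entries [%s, %s]\n",
              nrow(x), paste(unique(x$strategy), collapse = ","),
              paste(unique(x$method), collapse = ",")))
  cat(sprintf("  mean predictive ability %.3f, mean bias %.3f\n",
              mean(x$predictive_ability, na.rm = TRUE),
              mean(x$bias, na.rm = TRUE)))
  invisible(x)
}
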
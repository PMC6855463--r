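#' Deviance analysis of cross-validation metrics
#'
#' Compares genomic selection methods on a per-fold CV metric with linear
#' mixed models fitted by maximum likelihood:
#' `y = s + m + e` (no population-structure term), or
#' `y = s + p + m + e` with `with_structure = TRUE`, where `s` is the
#' cross-validation run (replicate x fold) random effect, `p` the random
#' interaction between training and validation populations (validation
#' cluster x absent cluster), `m` the fixed method effect. Each term is
#' tested by a likelihood-ratio test against the reduced model (methods on
#' `n_methods - 1` df; random terms on the naive 1 df chi-square, not the
#' boundary-corrected mixture). Method means are separated by Tukey's
#' studentized-range test on the balanced layout.
#'
#' @param cv `cv_result` (rows from several methods on one shared plan)
#' @param response `"predictive_ability"`, `"bias"` or `"accuracy"`
#' @param with_structure include the population-structure interaction
#'   random effect (use for the within/between-cluster strategies)
#' @return object of class `deviance_table`: list with `terms`
#'   (data.frame: term, df, deviance, p_value) and `means` (data.frame:
#'   method, mean, se, letters), plus the fitted full model
#' @export
deviance_analysis <- function(cv, response = c("predictive_ability", "bias",
                                               "accuracy"),
                              with_structure = FALSE) {
  response <- match.arg(response)
  stopifnot(is.data.frame(cv), response %in% names(cv))
  dat <- cv[!is.na(cv[[response]]), , drop = FALSE]
  if (nrow(dat) == 0) stop("response column '", response, "' is entirely missing")
  dat$.y <- dat[[response]]
  dat$method <- factor(dat$method)
  if (nlevels(dat$method) < 2) stop("need at least two methods")
  if (length(unique(dat$replicate)) < 2)
    stop("need at least two replicates: the cross-validation random effect is inestimable")
  dat$s <- factor(paste(dat$replicate, dat$fold, sep = "/"))
  if (with_structure) {
    if (all(is.na(dat$validation_cluster)))
      stop("with_structure = TRUE needs validation-cluster information")
    dat$p <- factor(paste(dat$validation_cluster, dat$absent_cluster, sep = "/"))
  }

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  ml_dev <- function(form) {
    has_ranef <- grepl("\\|", paste(deparse(form), collapse = ""))
    fit <- if (has_ranef)
      lme4::lmer(form, data = dat, REML = FALSE, control = ctrl)
    else
      stats::lm(form, data = dat)
    list(fit = fit, dev = -2 * as.numeric(stats::logLik(fit)))
  }
  full_form <- if (with_structure) .y ~ method + (1 | s) + (1 | p)
               else .y ~ method + (1 | s)
  full <- ml_dev(full_form)
  drop_m <- ml_dev(if (with_structure) .y ~ 1 + (1 | s) + (1 | p) else .y ~ 1 + (1 | s))
  drop_s <- ml_dev(if (with_structure) .y ~ method + (1 | p) else .y ~ method)
  lrt <- function(red, df) {
    dev <- max(red$dev - full$dev, 0)
    c(deviance = dev, p_value = stats::pchisq(dev, df, lower.tail = FALSE))
  }
  terms <- data.frame(term = c("methods", "cross_validation"),
                      df = c(nlevels(dat$method) - 1L, 1L),
                      rbind(lrt(drop_m, nlevels(dat$method) - 1L), lrt(drop_s, 1L)),
                      stringsAsFactors = FALSE)
  if (with_structure) {
    drop_p <- ml_dev(.y ~ method + (1 | s))
    terms <- rbind(terms, data.frame(term = "population_structure", df = 1L,
                                     t(lrt(drop_p, 1L)), stringsAsFactors = FALSE))
  }
  rownames(terms) <- NULL

  means <- tukey_means(dat$.y, dat$method)
  structure(list(terms = terms, means = means, response = response,
                 with_structure = with_structure, model = full$fit),
            class = "deviance_table")
}

# Tukey studentized-range separation on a balanced one-way layout:
# method means, SD across fold entries (the display convention of GS
# method-comparison tables), and a compact letter display derived from the
# contiguous-run rule, valid here because all methods share the SE.
tukey_means <- function(y, method, alpha = 0.05) {
  method <- droplevels(factor(method))
  k <- nlevels(method)
  mns <- tapply(y, method, mean)
  sds <- tapply(y, method, stats::sd)
  ns <- tapply(y, method, length)
  df_res <- length(y) - k
  mse <- sum((y - mns[method])^2) / df_res
  ord <- order(mns, decreasing = TRUE)
  # pairwise Tukey p for sorted means; equal SE assumed (balanced CV layout)
  se_pair <- sqrt(mse / 2 * (1 / ns[ord] %o% rep(1, k) + rep(1, k) %o% (1 / ns[ord])))
  qstat <- abs(outer(mns[ord], mns[ord], "-")) / se_pair
  pmat <- stats::ptukey(qstat, nmeans = k, df = df_res, lower.tail = FALSE)
  # contiguous runs of mutually non-different means -> letters
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && pmat[i, j + 1] > alpha) j <- j + 1
    runs[[i]] <- i:j
  }
  runs <- runs[!vapply(seq_along(runs), function(i)
    any(vapply(runs[-i], function(r) all(runs[[i]] %in% r), TRUE)), TRUE)]
  letters_sorted <- rep("", k)
  for (li in seq_along(runs))
    for (i in runs[[li]])
      letters_sorted[i] <- paste0(letters_sorted[i], LETTERS[li])
  out <- data.frame(method = levels(method)[ord], mean = unname(mns[ord]),
                    sd = unname(sds[ord]), n = unname(ns[ord]),
                    se = unname(sqrt(mse / ns[ord])),
                    letters = letters_sorted, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.deviance_table <- function(x, ...) {
  cat(sprintf("Deviance analysis of %s%s\n", x$response,
              if (x$with_structure) " (with population-structure term)" else ""))
  tt <- x$terms
  tt$deviance <- round(tt$deviance, 2)
  tt$p_value <- signif(tt$p_value, 3)
  print(tt, row.names = FALSE)
  cat("Tukey mean separation (alpha = 0.05):\n")
  mm <- x$means
  mm$mean <- round(mm$mean, 4); mm$sd <- round(mm$sd, 4); mm$se <- round(mm$se, 4)
  print(mm, row.names = FALSE)
  invisible(x)
}

#' GEBV correlation matrix across methods
#'
#' Pearson correlations of the GEBV vectors of several fits (plus,
#' optionally, the stage-1 BLUPs) on their common individuals.
#'
#' @param fits named list of `gs_fit` objects (names become row labels)
#' @param blups optional named numeric vector of stage-1 BLUPs to append
#'   as an extra column/row `"BLUP"`
#' @return symmetric correlation matrix with unit diagonal
#' @export
gebv_correlation_matrix <- function(fits, blups = NULL) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$method, "")
  common <- Reduce(intersect, lapply(fits, function(f) names(f$g)))
  if (!is.null(blups)) common <- intersect(common, names(blups))
  if (length(common) < 3) stop("fewer than 3 common individuals across fits")
  M <- vapply(fits, function(f) f$g[common], numeric(length(common)))
  if (!is.null(blups)) M <- cbind(M, BLUP = blups[common])
  cc <- stats::cor(M)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Cohen's kappa selection-coincidence curve
#'
#' For each selection proportion SP, the top `ceiling(SP * n)` individuals
#' by each GEBV vector are coded selected (1) / unselected (0) and
#' agreement is summarised by Cohen's kappa,
#' `(p_o - p_e) / (1 - p_e)`, with chance agreement `p_e` from the
#' marginal selection proportions. Ties in GEBVs are broken by id order,
#' so the curve is deterministic.
#'
#' @param gebv_a,gebv_b named numeric vectors over a common id set
#' @param sp_grid selection proportions (default 1% to 30% in 1% steps)
#' @return `kappa_curve` data.frame with columns `sp`, `n_selected`,
#'   `kappa`
#' @export
kappa_selection <- function(gebv_a, gebv_b, sp_grid = seq(0.01, 0.30, by = 0.01)) {
  common <- intersect(names(gebv_a), names(gebv_b))
  if (length(common) == 0) stop("no common ids between the two GEBV vectors")
  a <- gebv_a[common]; b <- gebv_b[common]
  n <- length(common)
  if (n * min(sp_grid) < 1)
    stop("smallest selection proportion selects nobody at n = ", n)
  ord_a <- order(-a, seq_len(n))  # ties broken by id order
  ord_b <- order(-b, seq_len(n))
  kap <- vapply(sp_grid, function(sp) {
    ns <- ceiling(sp * n)
    sel_a <- sel_b <- logical(n)
    sel_a[ord_a[seq_len(ns)]] <- TRUE
    sel_b[ord_b[seq_len(ns)]] <- TRUE
    po <- mean(sel_a == sel_b)
    q <- ns / n
    pe <- q^2 + (1 - q)^2
    if (pe == 1) return(1)
    (po - pe) / (1 - pe)
  }, 0)
  out <- data.frame(sp = sp_grid, n_selected = ceiling(sp_grid * n), kappa = kap)
  class(out) <- c("kappa_curve", "data.frame")
  out
}
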
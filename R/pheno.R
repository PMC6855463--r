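#' Fit the stage-1 clonal mixed model
#'
#' Fits, by REML, the clonal model
#' `y = mu + clone (random) + location-year (fixed) + rep within
#' location-year (random) + residual`
#' to plot-level multi-environment trial records, and extracts per-clone
#' BLUPs with their prediction error variances (PEV, the conditional
#' variance of each clone effect), variance components, and fixed-effect
#' estimates. Deregression and heritability are computed downstream by
#' [deregress()] and [phenotypic_heritability()].
#'
#' @param trials data.frame with columns `clone`, `rep` and the trait,
#'   plus either `loc_year` or both `location` and `year`
#' @param trait name of the trait column (default `"trait_y"`)
#' @return object of class `clonal_estimates`: a list with `clones`
#'   (data.frame: clone, blup, pev, reliability, deregressed, flagged),
#'   `varcomp` (sigma2_clone, sigma2_rep, sigma2_resid), `h2_phen`
#'   (plot basis), `grand_mean`, `fixef` (location-year effects),
#'   `trait`, `n_records`, and the `lme4` fit in `$fit`.
#' @export
fit_clonal_lmm <- function(trials, trait = "trait_y") {
  stopifnot(is.data.frame(trials), trait %in% names(trials))
  if (!"loc_year" %in% names(trials)) {
    if (!all(c("location", "year") %in% names(trials)))
      stop("trials needs a loc_year column or location and year columns")
    trials$loc_year <- paste(trials$location, trials$year, sep = ":")
  }
  dat <- trials[!is.na(trials[[trait]]),
                c("clone", "loc_year", "rep", trait)]
  names(dat)[4] <- ".y"
  dat$clone <- factor(dat$clone)
  dat$loc_year <- factor(dat$loc_year)
  dat$rep_in_ly <- factor(paste(dat$loc_year, dat$rep, sep = "/"))
  if (nlevels(dat$clone) < 2)
    stop("need at least two clones with records for trait ", trait)

  # fixed-effect identifiability: every location-year must carry data
  empty <- levels(dat$loc_year)[table(dat$loc_year) == 0]
  if (length(empty))
    stop("location-year level(s) without records (aliased): ",
         paste(empty, collapse = ", "))

  # the rep term is dropped when it is degenerate: a single level, or one
  # record per level (inseparable from the residual)
  rep_ok <- nlevels(dat$rep_in_ly) > 1 && nlevels(dat$rep_in_ly) < nrow(dat)
  fe_part <- if (nlevels(dat$loc_year) > 1) ".y ~ loc_year + (1 | clone)"
             else ".y ~ 1 + (1 | clone)"
  form <- stats::as.formula(paste(fe_part,
                                  if (rep_ok) "+ (1 | rep_in_ly)" else ""))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  s2 <- stats::setNames(vc$vcov, vc$grp)
  sigma2_clone <- unname(s2["clone"])
  sigma2_rep <- if (rep_ok) unname(s2["rep_in_ly"]) else 0
  sigma2_resid <- unname(s2["Residual"])

  # BLUPs and exact PEVs from the dense solve of Henderson's mixed-model
  # equations at the REML variance components (lme4's conditional variances
  # omit the fixed-effect uncertainty that the coefficient-matrix inverse
  # carries, so the MME route is used directly; desk scale n keeps it cheap)
  X <- if (nlevels(dat$loc_year) > 1)
    stats::model.matrix(~loc_year, dat) else matrix(1, nrow(dat), 1)
  Z1 <- Matrix::sparse.model.matrix(~ 0 + clone, dat)
  # penalty floor keeps C invertible in the zero-residual limit (where the
  # intercept is collinear with the full set of clone dummies); the floor is
  # far below any PEV resolution of interest
  lam1 <- max(sigma2_resid / max(sigma2_clone, 1e-12), 1e-8)
  q1 <- ncol(Z1)
  blocks <- list(X, Z1)
  penalties <- c(rep(0, ncol(X)), rep(lam1, q1))
  if (rep_ok && sigma2_rep > 1e-10 * sigma2_resid) {
    Z2 <- Matrix::sparse.model.matrix(~ 0 + rep_in_ly, dat)
    blocks <- c(blocks, Z2)
    penalties <- c(penalties, rep(sigma2_resid / sigma2_rep, ncol(Z2)))
  }
  W <- do.call(cbind, lapply(blocks, methods::as, "generalMatrix"))
  C <- as.matrix(Matrix::crossprod(W)) + diag(penalties)
  Cinv <- solve(C)
  sol <- drop(Cinv %*% drop(Matrix::crossprod(W, dat$.y)))
  ix <- ncol(X) + seq_len(q1)
  blup <- sol[ix]
  pev <- sigma2_resid * diag(Cinv)[ix]
  clones <- data.frame(clone = levels(dat$clone), blup = blup, pev = pev,
                       reliability = NA_real_, deregressed = NA_real_,
                       flagged = FALSE, stringsAsFactors = FALSE)
  rownames(clones) <- NULL

  fe <- lme4::fixef(fit)
  structure(list(clones = clones,
                 varcomp = c(sigma2_clone = sigma2_clone,
                             sigma2_rep = sigma2_rep,
                             sigma2_resid = sigma2_resid),
                 h2_phen = sigma2_clone / (sigma2_clone + sigma2_rep + sigma2_resid),
                 grand_mean = unname(fe[1]),
                 fixef = fe,
                 trait = trait,
                 n_records = nrow(dat),
                 fit = fit),
            class = "clonal_estimates")
}

#' Deregress clone BLUPs
#'
#' Reliability is `1 - PEV / sigma2_clone`; the deregressed BLUP is
#' `BLUP / reliability`, undoing mixed-model shrinkage so the values can
#' serve as a genomic-selection response. Clones whose reliability is at
#' or below `floor` (including non-positive reliabilities from PEV >=
#' sigma2_clone) are flagged rather than dropped; flagged clones carry
#' `NA` deregressed values and are excluded from GS training by
#' [run_cv()].
#'
#' @param estimates `clonal_estimates` from [fit_clonal_lmm()]
#' @param floor reliability floor below which deregression is considered
#'   unstable (default 0.05)
#' @return the same object with `reliability`, `deregressed`, `flagged`
#'   filled in
#' @export
deregress <- function(estimates, floor = 0.05) {
  stopifnot(inherits(estimates, "clonal_estimates"))
  s2c <- estimates$varcomp[["sigma2_clone"]]
  if (s2c <= 0) stop("clone variance component is zero; cannot deregress")
  cl <- estimates$clones
  cl$reliability <- 1 - cl$pev / s2c
  cl$flagged <- cl$reliability <= floor
  cl$deregressed <- ifelse(cl$flagged, NA_real_, cl$blup / cl$reliability)
  estimates$clones <- cl
  estimates$reliability_floor <- floor
  estimates
}

#' Phenotypic heritability
#'
#' Plot basis (default): `sigma2_clone / (sigma2_clone + sigma2_rep +
#' sigma2_resid)`. Entry-mean basis divides rep and residual components by
#' the harmonic mean number of replicates/plots per clone.
#'
#' @param estimates `clonal_estimates`
#' @param basis `"plot"` or `"entry_mean"`
#' @return heritability in \[0, 1\]
#' @export
phenotypic_heritability <- function(estimates, basis = c("plot", "entry_mean")) {
  basis <- match.arg(basis)
  v <- estimates$varcomp
  if (sum(v) <= 0) stop("all variance components are zero")
  if (basis == "plot")
    return(unname(v["sigma2_clone"] / sum(v)))
  tab <- table(estimates$fit@frame$clone)
  nbar <- length(tab) / sum(1 / tab)   # harmonic mean plots per clone
  unname(v["sigma2_clone"] /
           (v["sigma2_clone"] + v["sigma2_rep"] / nbar + v["sigma2_resid"] / nbar))
}

#' @export
print.clonal_estimates <- function(x, ...) {
  cat(sprintf("clonal_estimates [%s]: %d clones, %d records\n",
              x$trait, nrow(x$clones), x$n_records))
  cat(sprintf("  variance components: clone %.4g, rep %.4g, residual %.4g (plot h2 = %.3f)\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3], x$h2_phen))
  if (!all(is.na(x$clones$deregressed)) || any(x$clones$flagged))
    cat(sprintf("  deregressed: %d clones, %d flagged (reliability <= %.2f)\n",
                sum(!x$clones$flagged), sum(x$clones$flagged),
                if (is.null(x$reliability_floor)) NA else x$reliability_floor))
  invisible(x)
}
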
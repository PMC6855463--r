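#' Fit a genomic prediction model
#'
#' Single entry point for the five whole-genome regression methods used in
#' clonal genomic selection. All fit the linear model
#' `y_d = mu + genetic value + e` on a training set of deregressed BLUPs,
#' but differ in how the genetic term is parameterised:
#'
#' * `"rrblup"` — ridge regression on centered marker dosages; marker
#'   effects share one normal prior, variance components by REML
#'   (algebraically identical to G-BLUP GEBVs).
#' * `"gblup"` — mixed model on the additive genomic relationship matrix
#'   G (VanRaden), REML via eigendecomposition.
#' * `"rkhs"` — the same mixed model on a Gaussian kernel K, capturing
#'   additive plus non-additive signal.
#' * `"bayesb"` — Gibbs sampler with a per-marker mixture prior: point
#'   mass at zero with probability `1 - pi`, scaled-t slab otherwise
#'   (marker-specific variances); `pi` is sampled with a Beta prior.
#' * `"blasso"` — Bayesian LASSO (double-exponential marker prior via the
#'   exponential-mixture hierarchy, gamma hyperprior on lambda^2).
#'
#' @param y named numeric vector of training responses (deregressed
#'   BLUPs); names are clone ids
#' @param geno `genotype_matrix` (complete) covering at least the training
#'   ids; required for rrblup/bayesb/blasso, used to build the kernel for
#'   gblup/rkhs when `kernel` is not supplied
#' @param kernel optional `kinship_matrix` for gblup (additive_G) or rkhs
#'   (gaussian_K); may contain non-training individuals (used by
#'   [predict.gs_fit()])
#' @param method one of `"gblup"`, `"rrblup"`, `"rkhs"`, `"bayesb"`,
#'   `"blasso"`
#' @param n_iter,burn_in,thin MCMC settings for the Bayesian methods
#'   (defaults 10000 / 2000 / 10)
#' @param seed integer seed for the Gibbs samplers
#' @param h Gaussian-kernel bandwidth when rkhs builds its own kernel
#' @return object of class `gs_fit`; see [predict.gs_fit()],
#'   [summary.gs_fit()], [coef.gs_fit()]. Key fields: `mu`, `g` (training
#'   GEBVs), `beta` (marker effects, marker methods), `varcomp`
#'   (`sigma2_g`, `sigma2_e`, and `sigma2_beta` for marker methods),
#'   `h2_gen`, `pi` (bayesb), `lambda` (blasso), `chains` (retained MCMC
#'   samples of the variance parameters).
#' @export
gs_fit <- function(y, geno = NULL, kernel = NULL,
                   method = c("gblup", "rrblup", "rkhs", "bayesb", "blasso"),
                   n_iter = 10000, burn_in = 2000, thin = 10, seed = 1L,
                   h = 1) {
  method <- match.arg(method)
  if (is.null(names(y))) stop("y must be named by clone id")
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 20 && method %in% c("rrblup", "bayesb", "blasso"))
    warning("fewer than 20 training records for a marker-based method")
  if (stats::var(y) == 0) stop("training response is constant")

  if (method %in% c("gblup", "rkhs")) {
    if (is.null(kernel)) {
      if (is.null(geno)) stop("supply geno or kernel for ", method)
      kernel <- if (method == "gblup") additive_G(geno) else gaussian_K(geno, h = h)
    }
    if (max(abs(unclass(kernel) - t(unclass(kernel)))) > 1e-8)
      stop("kernel must be symmetric")
    miss <- setdiff(names(y), rownames(kernel))
    if (length(miss)) stop("kernel lacks training individuals: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    Ktt <- unclass(kernel)[names(y), names(y)]
    fit <- reml_kernel(y, Ktt)
    if (stats::var(fit$g) < 1e-12 * stats::var(y))
      warning("GEBVs are essentially flat; the kernel carries no contrast")
    out <- list(method = toupper(method), mu = fit$mu,
                g = stats::setNames(fit$g, names(y)), beta = NULL,
                varcomp = list(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e),
                h2_gen = fit$h2, pi = NULL, lambda = NULL, chains = NULL,
                train_ids = names(y), kernel = kernel,
                kernel_kind = attr(kernel, "kind"))
  } else {
    if (is.null(geno)) stop("supply geno for ", method)
    miss <- setdiff(names(y), sample_ids(geno))
    if (length(miss)) stop("genotypes lack training individuals: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    cd <- centered_dosage(geno)
    center <- 2 * (cd$p - 0.5)
    denom <- 2 * sum(cd$p * (1 - cd$p))
    Zc <- cd$Zc[names(y), , drop = FALSE]
    if (method == "rrblup") {
      G0 <- tcrossprod(Zc) / denom
      fit <- reml_kernel(y, G0)
      # back-transform to marker effects: beta = sigma2_beta * Z' V^-1 (y - mu)
      beta <- drop(crossprod(Zc, fit$vinv_r)) / denom
      g <- drop(Zc %*% beta)
      out <- list(method = "RRBLUP", mu = fit$mu,
                  g = stats::setNames(g, names(y)),
                  beta = stats::setNames(beta, geno$map$marker),
                  varcomp = list(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                                 sigma2_beta = fit$sigma2_g / denom),
                  h2_gen = fit$h2, pi = NULL, lambda = NULL, chains = NULL,
                  train_ids = names(y))
    } else {
      if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
      set.seed(as.integer(seed))
      mc <- if (method == "bayesb")
        bayesb_gibbs(y, Zc, n_iter, burn_in, thin)
      else
        blasso_gibbs(y, Zc, n_iter, burn_in, thin)
      g <- drop(Zc %*% mc$beta)
      s2g <- mean(mc$chain_var_g)
      s2e <- mean(mc$chain_sigma_e2)
      out <- list(method = toupper(method), mu = mc$mu,
                  g = stats::setNames(g, names(y)),
                  beta = stats::setNames(mc$beta, geno$map$marker),
                  varcomp = list(sigma2_g = s2g, sigma2_e = s2e),
                  h2_gen = s2g / (s2g + s2e),
                  pi = if (method == "bayesb") mean(mc$chain_pi) else NULL,
                  lambda = if (method == "blasso") mean(sqrt(mc$chain_lambda2)) else NULL,
                  chains = list(sigma_e2 = mc$chain_sigma_e2,
                                var_g = mc$chain_var_g,
                                pi = if (method == "bayesb") mc$chain_pi else NULL,
                                lambda2 = if (method == "blasso") mc$chain_lambda2 else NULL),
                  train_ids = names(y),
                  mcmc = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                              seed = as.integer(seed)))
    }
    out$marker_center <- center
    out$marker_ids <- geno$map$marker
  }
  out$y <- y
  class(out) <- "gs_fit"
  out
}

# REML for y = 1*mu + g + e, g ~ N(0, sigma2_g * K), via eigendecomposition
# of K; the variance ratio delta = sigma2_e / sigma2_g is profiled out of
# the restricted likelihood and optimised on the log scale.
reml_kernel <- function(y, K) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  xr <- drop(crossprod(U, rep(1, n)))
  restr_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    sxx <- sum(w * xr^2)
    mu <- sum(w * xr * yr) / sxx
    r <- yr - xr * mu
    s2g <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(s2g) - sum(log(w)) + log(sxx) + (n - 1))
  }
  opt <- stats::optimize(restr_ll, c(-14, 14), maximum = TRUE, tol = 1e-10)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  mu <- sum(w * xr * yr) / sum(w * xr^2)
  r <- yr - xr * mu
  s2g <- sum(w * r^2) / (n - 1)
  s2e <- delta * s2g
  # V^-1 (y - mu) in the original basis, then g = sigma2_g K V^-1 (y - mu)
  vinv_r <- drop(U %*% (w * r)) / s2g
  g <- s2g * drop(K %*% vinv_r)
  list(mu = mu, sigma2_g = s2g, sigma2_e = s2e, h2 = s2g / (s2g + s2e),
       g = g, vinv_r = vinv_r, delta = delta, reml_ll = opt$objective)
}

#' Predict GEBVs for new individuals
#'
#' Marker methods compute `Z_new %*% beta` with the training centering;
#' kernel methods project through the relationship matrix:
#' `K[new, train] %*% solve(K[train, train]) %*% g_train`
#' (ridge-stabilised). Predicting the training individuals reproduces the
#' fitted GEBVs.
#'
#' @param object `gs_fit`
#' @param newdata for marker methods, a `genotype_matrix` (or dosage
#'   matrix with marker columns) containing the training marker set; for
#'   kernel methods, a character vector of ids present in the stored
#'   kernel, or a kinship rows matrix `K[new, ]` whose columns cover the
#'   training ids. Defaults to the training set.
#' @param ... unused
#' @return named numeric vector of GEBVs
#' @export
predict.gs_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$g + 0)
  if (!is.null(object$beta)) {
    Z <- if (inherits(newdata, "genotype_matrix")) newdata$dosage else as.matrix(newdata)
    miss <- setdiff(object$marker_ids, colnames(Z))
    if (length(miss))
      stop("prediction genotypes lack ", length(miss), " training marker(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    Z <- Z[, object$marker_ids, drop = FALSE]
    Zc <- sweep(Z, 2, object$marker_center)
    return(drop(Zc %*% object$beta))
  }
  K <- unclass(object$kernel)
  if (is.character(newdata)) {
    miss <- setdiff(newdata, rownames(K))
    if (length(miss)) stop("kernel lacks individual(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    Krows <- K[newdata, object$train_ids, drop = FALSE]
  } else {
    Krows <- as.matrix(newdata)[, object$train_ids, drop = FALSE]
  }
  Ktt <- K[object$train_ids, object$train_ids]
  diag(Ktt) <- diag(Ktt) + 1e-8
  drop(Krows %*% solve(Ktt, object$g))
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit [%s]: %d training clones, h2_gen = %.3f\n",
              x$method, length(x$train_ids), x$h2_gen))
  invisible(x)
}

#' @export
summary.gs_fit <- function(object, ...) {
  cat(sprintf("Genomic prediction fit: %s\n", object$method))
  cat(sprintf("  training clones: %d\n", length(object$train_ids)))
  cat(sprintf("  intercept: %.4g\n", object$mu))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2_gen = %.3f\n",
              object$varcomp$sigma2_g, object$varcomp$sigma2_e, object$h2_gen))
  if (!is.null(object$varcomp$sigma2_beta))
    cat(sprintf("  sigma2_beta = %.4g over %d markers\n",
                object$varcomp$sigma2_beta, length(object$beta)))
  if (!is.null(object$pi)) cat(sprintf("  posterior mean pi = %.3f\n", object$pi))
  if (!is.null(object$lambda)) cat(sprintf("  posterior mean lambda = %.2f\n", object$lambda))
  invisible(object)
}

#' @export
coef.gs_fit <- function(object, ...) {
  if (!is.null(object$beta)) object$beta else object$g
}

#' @export
fitted.gs_fit <- function(object, ...) object$mu + object$g

#' @export
residuals.gs_fit <- function(object, ...) object$y - object$mu - object$g

#' Raftery-Lewis MCMC run-length diagnostic
#'
#' Run-length diagnostic on a scalar chain (here typically the residual
#' variance samples of a Gibbs sampler): how many iterations are needed to
#' estimate the `q` quantile to within `r` with probability `s`. Wraps the
#' standard two-state Markov chain computation; chains shorter than the
#' minimum `Nmin = ceiling(qnorm((1+s)/2)^2 * q * (1-q) / r^2)` raise an
#' informative error. Constant chains are degenerate and rejected.
#'
#' @param chain numeric vector of MCMC samples
#' @param q quantile of interest (default 0.025)
#' @param r tolerated error on the quantile estimate (default 0.005)
#' @param s required probability of achieving `r` (default 0.95)
#' @return list with `burn_in` (M), `n_required` (N), `n_min` (Nmin) and
#'   `dependence_factor` (I = (M+N)/Nmin)
#' @export
raftery_lewis <- function(chain, q = 0.025, r = 0.005, s = 0.95) {
  n_min <- ceiling(stats::qnorm((1 + s) / 2)^2 * q * (1 - q) / r^2)
  if (length(unique(chain)) == 1)
    stop("degenerate (constant) chain; diagnostic undefined")
  if (length(chain) < n_min)
    stop("chain too short for the Raftery-Lewis diagnostic: need at least ",
         n_min, " samples, got ", length(chain))
  res <- coda::raftery.diag(coda::mcmc(chain), q = q, r = r, s = s)$resmatrix
  list(burn_in = unname(res[1, "M"]), n_required = unname(res[1, "N"]),
       n_min = unname(res[1, "Nmin"]), dependence_factor = unname(res[1, "I"]))
}
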
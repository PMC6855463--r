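# Shared fixtures, built in code. The cache lives for one suite run so the
# heavier simulated panels are generated once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small structured panel with phenotypes: 2 clusters x 60, fst 0.3
small_panel <- function() cached("small_panel", {
  cfg <- sim_config(n_clusters = 2, n_per_cluster = 60, fst = 0.30,
                    n_markers = 500, n_chromosomes = 4, missing_rate = 0.05,
                    n_qtl = 40, h2_additive = 0.40, nonadditive_fraction = 0,
                    trial_layouts = list(trial_layout("RCBD", 3, "loc1", 2013),
                                         trial_layout("RCBD", 3, "loc2", 2014)),
                    seed = 11)
  geno <- simulate_structured_genotypes(cfg)
  ph <- simulate_phenotypes(geno, cfg)
  est <- deregress(fit_clonal_lmm(ph$trials))
  qc <- qc_genotypes(geno)
  list(cfg = cfg, geno = geno, qc = qc, trials = ph$trials, truth = ph$truth,
       est = est, yd = na.omit(setNames(est$clones$deregressed, est$clones$clone)))
})

# unstructured HWE panel without missingness
panmictic_panel <- function(n = 100, m = 400, seed = 5) {
  cfg <- sim_config(n_clusters = 1, n_per_cluster = n, fst = 0,
                    n_markers = m, n_chromosomes = 2, missing_rate = 0,
                    n_qtl = 20, h2_additive = 0.5, nonadditive_fraction = 0,
                    seed = seed)
  simulate_structured_genotypes(cfg)
}

# dense solve of Henderson's mixed-model equations for
# y = X b + Z1 u_clone + Z2 u_rep + e at given variance components;
# independent oracle for the stage-1 BLUP/PEV extraction
mme_solve <- function(dat, trait, s2c, s2r, s2e) {
  y <- dat[[trait]]
  X <- if (length(unique(dat$loc_year)) > 1)
    stats::model.matrix(~loc_year, transform(dat, loc_year = factor(loc_year)))
  else matrix(1, nrow(dat), 1)
  Z1 <- stats::model.matrix(~ 0 + clone, transform(dat, clone = factor(clone)))
  Z2 <- stats::model.matrix(~ 0 + r,
          transform(dat, r = factor(paste(loc_year, rep, sep = "/"))))
  lam1 <- s2e / s2c
  lam2 <- if (s2r > 1e-10) s2e / s2r else Inf
  q1 <- ncol(Z1); q2 <- ncol(Z2)
  if (is.finite(lam2)) {
    C <- rbind(
      cbind(crossprod(X), crossprod(X, Z1), crossprod(X, Z2)),
      cbind(crossprod(Z1, X), crossprod(Z1) + lam1 * diag(q1), crossprod(Z1, Z2)),
      cbind(crossprod(Z2, X), crossprod(Z2, Z1), crossprod(Z2) + lam2 * diag(q2)))
    rhs <- c(crossprod(X, y), crossprod(Z1, y), crossprod(Z2, y))
  } else {
    C <- rbind(cbind(crossprod(X), crossprod(X, Z1)),
               cbind(crossprod(Z1, X), crossprod(Z1) + lam1 * diag(q1)))
    rhs <- c(crossprod(X, y), crossprod(Z1, y))
  }
  Cinv <- solve(C)
  sol <- Cinv %*% rhs
  ix <- ncol(X) + seq_len(q1)
  list(blup = setNames(drop(sol[ix]), sub("^clone", "", colnames(Z1))),
       pev = setNames(s2e * diag(Cinv)[ix], sub("^clone", "", colnames(Z1))),
       fixed = drop(sol[seq_len(ncol(X))]))
}

# balanced toy trial: k clones x r reps in one location-year, fixed effects
toy_trial <- function(n_clones = 4, n_reps = 2, seed = 42,
                      s2c = 4, s2r = 1, s2e = 1) {
  set.seed(seed)
  clones <- paste0("cl", seq_len(n_clones))
  g <- rnorm(n_clones, 0, sqrt(s2c))
  r_eff <- rnorm(n_reps, 0, sqrt(s2r))
  dat <- expand.grid(clone = clones, rep = seq_len(n_reps),
                     stringsAsFactors = FALSE)
  dat$location <- "loc1"; dat$year <- 2013
  dat$loc_year <- "loc1:2013"
  dat$block <- dat$rep
  dat$trait_y <- 10 + g[match(dat$clone, clones)] + r_eff[dat$rep] +
    rnorm(nrow(dat), 0, sqrt(s2e))
  dat
}
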
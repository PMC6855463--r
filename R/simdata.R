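#' Simulation configuration
#'
#' Describes the stated world the simulator emulates: a germplasm panel of
#' divergent subpopulations genotyped at biallelic SNPs, phenotyped for a
#' quantitative trait with mixed additive/non-additive architecture in
#' clonally replicated multi-environment trials. Defaults mirror a
#' cassava-type training population: five clusters of 162/175/185/155/211
#' clones, 18 chromosomes, plot-basis additive heritability 0.34.
#'
#' @param n_clusters number of subpopulations
#' @param n_per_cluster clone count per cluster (recycled to `n_clusters`);
#'   zeros are an error
#' @param fst Balding-Nichols divergence of each cluster from the
#'   ancestral pool, in \[0, 1) (recycled); 0 gives panmixia
#' @param n_markers,n_chromosomes marker panel size and genome split
#' @param maf_floor minimum realized minor allele frequency at generation
#'   (before missingness is added)
#' @param missing_rate per-cell missing-call probability
#' @param n_qtl number of causal markers (must be <= n_markers, and >= 2
#'   when `nonadditive_fraction > 0`)
#' @param h2_additive plot-basis narrow-sense heritability target:
#'   additive variance over clone + rep + residual variance
#' @param nonadditive_fraction fraction of total genetic variance from
#'   dominance plus additive-by-additive epistasis
#' @param rep_var_fraction share of the non-genetic plot variance assigned
#'   to replicate effects (the rest is residual)
#' @param trial_layouts list of layouts from [trial_layout()]
#' @param n_checks number of replicated check clones in augmented designs
#' @param seed integer seed; all randomness fans out from it
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_clusters = 5,
                       n_per_cluster = c(162, 175, 185, 155, 211),
                       fst = 0.15,
                       n_markers = 5000,
                       n_chromosomes = 18,
                       maf_floor = 0.05,
                       missing_rate = 0.10,
                       n_qtl = 200,
                       h2_additive = 0.34,
                       nonadditive_fraction = 0.30,
                       rep_var_fraction = 0.20,
                       trial_layouts = list(
                         trial_layout("RCBD", n_reps = 3, location = "loc1", year = 2013),
                         trial_layout("RCBD", n_reps = 3, location = "loc2", year = 2013),
                         trial_layout("ABD", n_reps = 10, location = "loc1", year = 2014),
                         trial_layout("ABD", n_reps = 10, location = "loc2", year = 2014)),
                       n_checks = 5,
                       seed = 1L) {
  n_per_cluster <- rep_len(n_per_cluster, n_clusters)
  fst <- rep_len(fst, n_clusters)
  stopifnot(n_clusters >= 1, n_markers >= 1, n_chromosomes >= 1,
            maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1,
            n_qtl >= 1, n_qtl <= n_markers,
            h2_additive > 0, h2_additive <= 1,
            nonadditive_fraction >= 0, nonadditive_fraction < 1,
            rep_var_fraction >= 0, rep_var_fraction <= 1,
            all(fst >= 0), all(fst < 1),
            length(trial_layouts) >= 1)
  if (any(n_per_cluster <= 0))
    stop("n_per_cluster must be positive for every cluster")
  if (nonadditive_fraction > 0 && n_qtl < 2)
    stop("nonadditive_fraction > 0 requires n_qtl >= 2 (no epistatic pairs otherwise)")
  structure(list(n_clusters = n_clusters, n_per_cluster = n_per_cluster,
                 fst = fst, n_markers = n_markers,
                 n_chromosomes = n_chromosomes, maf_floor = maf_floor,
                 missing_rate = missing_rate, n_qtl = n_qtl,
                 h2_additive = h2_additive,
                 nonadditive_fraction = nonadditive_fraction,
                 rep_var_fraction = rep_var_fraction,
                 trial_layouts = trial_layouts, n_checks = n_checks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Trial layout descriptor
#'
#' @param design "RCBD" (all clones in every replicate block) or "ABD"
#'   (augmented: checks in every block, test entries once each)
#' @param n_reps replicate blocks (RCBD) or blocks / check replication (ABD)
#' @param location,year environment labels; their combination is the
#'   fixed location-year effect of the stage-1 model
#' @export
trial_layout <- function(design = c("RCBD", "ABD"), n_reps = 3,
                         location = "loc1", year = 2013) {
  design <- match.arg(design)
  stopifnot(n_reps >= 1)
  list(design = design, n_reps = as.integer(n_reps),
       location = as.character(location), year = as.integer(year))
}

#' Simulate structured SNP genotypes
#'
#' Draws per-cluster allele frequencies from a Balding-Nichols
#' distribution around ancestral frequencies (Beta with parameters
#' `p(1-F)/F`, `(1-p)(1-F)/F` for divergence `F`), then Hardy-Weinberg
#' genotypes within each cluster. Markers whose realized minor allele
#' frequency falls below `maf_floor` are redrawn. Missing calls are then
#' inserted uniformly at `missing_rate`. Markers are spread evenly over
#' chromosomes with ordered positions.
#'
#' @param config a [sim_config()]
#' @return `genotype_matrix`; attribute `sim_truth` carries the cluster
#'   labels and the complete (pre-missingness) dosage matrix used later by
#'   [simulate_phenotypes()].
#' @export
simulate_structured_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$n_per_cluster)
  m <- config$n_markers
  ids <- sprintf("clone_%04d", seq_len(n))
  labels <- rep(seq_len(config$n_clusters), config$n_per_cluster)
  names(labels) <- ids

  draw_markers <- function(mm) {
    p_anc <- stats::runif(mm, max(config$maf_floor, 0.05), 1 - max(config$maf_floor, 0.05))
    dos <- matrix(0, n, mm)
    for (k in seq_len(config$n_clusters)) {
      Fk <- config$fst[k]
      pk <- if (Fk == 0) p_anc else
        stats::rbeta(mm, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
      pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
      rows <- which(labels == k)
      dos[rows, ] <- matrix(stats::rbinom(length(rows) * mm, 2, rep(pk, each = length(rows))) - 1,
                            length(rows), mm)
    }
    dos
  }

  dosage <- draw_markers(m)
  # enforce the realized-MAF floor (before missingness)
  for (iter in 1:50) {
    p <- (colMeans(dosage) + 1) / 2
    bad <- which(pmin(p, 1 - p) < config$maf_floor - 1e-12)
    if (length(bad) == 0) break
    dosage[, bad] <- draw_markers(length(bad))
  }
  if (length(bad <- which(pmin(p <- (colMeans(dosage) + 1) / 2, 1 - p) < config$maf_floor - 1e-12)))
    warning(length(bad), " markers remain below the MAF floor after redraws")

  rownames(dosage) <- ids
  colnames(dosage) <- sprintf("snp_%05d", seq_len(m))
  complete <- dosage
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < config$missing_rate
    dosage[miss] <- NA
  }

  chrom <- rep(seq_len(config$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(5e7, length(ix)))), use.names = FALSE)
  map <- data.frame(marker = colnames(dosage), chrom = as.character(chrom),
                    pos = pos, stringsAsFactors = FALSE)

  geno <- genotype_matrix(dosage, map)
  # align the truth dosages with the (possibly reordered) marker map
  complete <- complete[, geno$map$marker, drop = FALSE]
  attr(geno, "sim_truth") <- list(cluster_labels = labels, complete_dosage = complete)
  geno
}

#' Simulate clonal multi-trial phenotypes
#'
#' Samples additive QTL effects (plus dominance deviations and pairwise
#' additive-by-additive epistasis when `nonadditive_fraction > 0`, scaled
#' so the non-additive share of genetic variance matches the
#' configuration), then lays plot records out over the configured trials:
#' plot value = grand mean + total genetic value + location-year effect +
#' replicate effect + residual. Replicate and residual variances are
#' solved so the plot-basis additive heritability equals `h2_additive`;
#' at `h2_additive = 1` with no non-additive variance the records are the
#' breeding values exactly.
#'
#' @param geno genotype_matrix from [simulate_structured_genotypes()] (its
#'   complete pre-missingness dosages are used), or any complete matrix
#' @param config a [sim_config()]
#' @return list with `trials` (a plot-level `data.frame`: clone, location,
#'   year, loc_year, rep, block, design, trait_y) and `truth` (class
#'   `simulation_truth`: breeding values, total genetic values, QTL
#'   indices/effects, cluster labels, realized heritability, variance
#'   components)
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  st <- attr(geno, "sim_truth")
  Z <- if (!is.null(st$complete_dosage)) st$complete_dosage else geno$dosage
  if (anyNA(Z))
    stop("phenotype simulation needs complete dosages; pass the simulator output or an imputed matrix")
  if (config$nonadditive_fraction > 0 && config$n_qtl < 2)
    stop("nonadditive_fraction > 0 requires n_qtl >= 2")
  set.seed(config$seed + 1000003L)
  n <- nrow(Z)
  ids <- rownames(Z)
  Zc <- sweep(Z, 2, colMeans(Z))

  qtl <- sort(sample.int(ncol(Z), config$n_qtl))
  a <- stats::rnorm(config$n_qtl)
  tbv <- drop(Zc[, qtl, drop = FALSE] %*% a)
  tbv <- tbv - mean(tbv)
  var_a <- stats::var(tbv)
  if (var_a <= 0) stop("degenerate additive values: all QTL monomorphic")

  dom <- epi <- rep(0, n)
  if (config$nonadditive_fraction > 0) {
    target_na <- var_a * config$nonadditive_fraction / (1 - config$nonadditive_fraction)
    H <- (Z[, qtl, drop = FALSE] == 0) * 1
    H <- sweep(H, 2, colMeans(H))
    dom <- drop(H %*% stats::rnorm(config$n_qtl))
    pairs <- cbind(sample(config$n_qtl), sample(config$n_qtl))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    W <- Zc[, qtl[pairs[, 1]], drop = FALSE] * Zc[, qtl[pairs[, 2]], drop = FALSE]
    W <- sweep(W, 2, colMeans(W))
    epi <- drop(W %*% stats::rnorm(nrow(pairs)))
    scale_to <- function(x, v) {
      if (stats::var(x) <= 1e-12) return(rep(0, length(x)))
      (x - mean(x)) * sqrt(v / stats::var(x))
    }
    dom <- scale_to(dom, target_na / 2)
    epi <- scale_to(epi, target_na / 2)
  }
  g_tot <- tbv + dom + epi
  var_na <- stats::var(dom) + stats::var(epi)

  # plot-basis: h2_additive = var_a / (var_a + var_na + s2_rep + s2_res)
  tot_nongen <- var_a / config$h2_additive - var_a - var_na
  if (tot_nongen < -1e-8)
    stop("h2_additive and nonadditive_fraction are incompatible: ",
         "non-genetic variance would be negative")
  tot_nongen <- max(tot_nongen, 0)
  s2_rep <- config$rep_var_fraction * tot_nongen
  s2_res <- tot_nongen - s2_rep
  sd_locyear <- sqrt(0.5 * tot_nongen)

  checks <- ids[seq_len(min(config$n_checks, n))]
  rows <- vector("list", length(config$trial_layouts))
  for (t_i in seq_along(config$trial_layouts)) {
    lay <- config$trial_layouts[[t_i]]
    ly_eff <- stats::rnorm(1, 0, sd_locyear)
    if (lay$design == "RCBD") {
      plots <- do.call(rbind, lapply(seq_len(lay$n_reps), function(r)
        data.frame(clone = ids, rep = r, block = r, stringsAsFactors = FALSE)))
    } else {
      entries <- setdiff(ids, checks)
      blk_of <- sample(rep_len(seq_len(lay$n_reps), length(entries)))
      plots <- do.call(rbind, lapply(seq_len(lay$n_reps), function(b)
        data.frame(clone = c(checks, entries[blk_of == b]), rep = b, block = b,
                   stringsAsFactors = FALSE)))
    }
    rep_eff <- stats::rnorm(lay$n_reps, 0, sqrt(s2_rep))
    plots$location <- lay$location
    plots$year <- lay$year
    plots$design <- lay$design
    plots$trait_y <- g_tot[match(plots$clone, ids)] + ly_eff +
      rep_eff[plots$rep] + stats::rnorm(nrow(plots), 0, sqrt(s2_res))
    rows[[t_i]] <- plots
  }
  trials <- do.call(rbind, rows)
  trials$loc_year <- paste(trials$location, trials$year, sep = ":")
  trials <- trials[, c("clone", "location", "year", "loc_year", "rep",
                       "block", "design", "trait_y")]
  rownames(trials) <- NULL

  truth <- structure(list(
    true_breeding_values = stats::setNames(tbv, ids),
    true_total_genetic_values = stats::setNames(g_tot, ids),
    qtl_indices = qtl,
    qtl_effects = a,
    cluster_labels = st$cluster_labels,
    realized_h2 = var_a / (var_a + var_na + s2_rep + s2_res),
    var_components = list(additive = var_a, nonadditive = var_na,
                          rep = s2_rep, residual = s2_res)),
    class = "simulation_truth")
  list(trials = trials, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d clones, %d QTL, realized plot h2 = %.3f (non-additive share %.2f)\n",
              length(x$true_breeding_values), length(x$qtl_indices), x$realized_h2,
              x$var_components$nonadditive /
                (x$var_components$additive + x$var_components$nonadditive)))
  invisible(x)
}
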
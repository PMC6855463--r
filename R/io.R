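#' Read genotypes from VCF or a delimited dosage matrix
#'
#' VCF genotypes are mapped `0/0 -> -1`, `0/1` or `1/0 -> 0`,
#' `1/1 -> 1`, missing GT -> `NA`; multi-allelic records are skipped with
#' a counted warning (requires the VariantAnnotation package). Dosage CSVs
#' are individuals x markers with an id column first and marker ids in the
#' header; an optional `map` data.frame or CSV path (`marker`, `chrom`,
#' `pos`) places the markers.
#'
#' @param path file path
#' @param format `"vcf"` or `"dosage_csv"`
#' @param map optional marker map for dosage CSVs (data.frame or CSV path)
#' @return `genotype_matrix`
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_csv"), map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path)
    nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(v))
    if (any(nalt > 1)) {
      warning(sum(nalt > 1), " multi-allelic record(s) skipped")
      v <- v[nalt <= 1]
    }
    gt <- VariantAnnotation::geno(v)$GT
    if (is.null(gt)) stop("malformed VCF: no GT field")
    if (anyDuplicated(colnames(gt))) stop("duplicate sample ids in VCF")
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dos[gt == "0/0"] <- -1
    dos[gt %in% c("0/1", "1/0")] <- 0
    dos[gt == "1/1"] <- 1
    rr <- SummarizedExperiment::rowRanges(v)
    map <- data.frame(marker = rownames(gt),
                      chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr), stringsAsFactors = FALSE)
    genotype_matrix(t(dos), map)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(tab[[1]])) stop("duplicate sample ids in dosage matrix")
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- tab[[1]]
    if (is.character(map)) map <- utils::read.csv(map, stringsAsFactors = FALSE)
    genotype_matrix(dos, map)
  }
}

#' Write genotypes
#'
#' `write_genotypes_vcf()` emits a minimal GT-only VCF (dosage -1/0/1
#' mapped back to 0/0, 0/1, 1/1; `NA` to `./.`; positions 1-based);
#' `write_genotypes_csv()` emits the delimited dosage matrix (id column
#' first) and, optionally, the marker map next to it.
#'
#' @param geno genotype_matrix
#' @param path output file
#' @param map_path optional path for the marker map CSV
#' @return the path, invisibly
#' @export
write_genotypes_vcf <- function(geno, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  d <- geno$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt <- matrix("./.", nrow(d), ncol(d))
  obs <- !is.na(d)
  gt[obs] <- gt_code[d[obs] + 2]
  lines <- paste(geno$map$chrom, geno$map$pos, geno$map$marker, "A", "G",
                 ".", ".", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
write_genotypes_csv <- function(geno, path, map_path = NULL) {
  out <- data.frame(id = rownames(geno$dosage), geno$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(map_path)) utils::write.csv(geno$map, map_path, row.names = FALSE)
  invisible(path)
}

#' Write a kinship matrix as delimited text
#'
#' @param kin kinship_matrix
#' @param path output CSV (ids in header row and first column)
#' @export
write_kinship_csv <- function(kin, path) {
  out <- data.frame(id = rownames(kin), unclass(kin), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis with the study's
#' standard defaults: call rate 0.90, MAF 0.05, DAPC variance thresholds
#' 0.85 / 0.94, MCMC 10000 / 2000 / 10, CV folds 5 (random) or 3
#' (structured) x 3 replicates.
#'
#' @param genotype_path,phenotype_path input files (NULL to simulate)
#' @param sim `sim_config` used when inputs are simulated
#' @param out_dir output directory
#' @param traits trait column names
#' @param min_call_rate,min_maf marker QC thresholds
#' @param dapc_k,pc_variance_threshold,df_variance_threshold DAPC settings
#' @param methods genomic prediction methods to run
#' @param strategies cross-validation strategies to run
#' @param cv_replicates CV replicates
#' @param n_iter,burn_in,thin MCMC settings
#' @param seed master seed; per-stage child seeds are derived from it
#' @return list of class `run_config`
#' @export
run_config <- function(genotype_path = NULL, phenotype_path = NULL,
                       sim = sim_config(), out_dir = tempfile("gs_run_"),
                       traits = "trait_y",
                       min_call_rate = 0.90, min_maf = 0.05,
                       dapc_k = "auto", pc_variance_threshold = 0.85,
                       df_variance_threshold = 0.94,
                       methods = c("gblup", "rrblup", "rkhs"),
                       strategies = c("S1_random", "S3_leave_cluster_out"),
                       cv_replicates = 3,
                       n_iter = 10000, burn_in = 2000, thin = 10,
                       seed = 1L) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1, min_maf >= 0, min_maf < 0.5,
            pc_variance_threshold > 0, pc_variance_threshold <= 1,
            df_variance_threshold > 0, df_variance_threshold <= 1)
  structure(as.list(environment()), class = "run_config")
}

child_seed <- function(seed, stage) {
  # fixed per-stage derivation so stages can be rerun in isolation
  offsets <- c(simulate = 11L, pheno = 23L, qc = 37L, dapc = 53L,
               fit = 71L, cv = 97L)
  (as.integer(seed) * 1103L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full genomic-selection pipeline
#'
#' Simulate (or ingest) genotypes and trial phenotypes, fit the stage-1
#' clonal model and deregress, run marker QC and build both kernels,
#' infer DAPC clusters, cross-validate every requested method under every
#' requested strategy, and run the method-comparison deviance analysis.
#' All artifacts are written under `config$out_dir` with a JSON manifest.
#'
#' @param config `run_config`
#' @return list with the key objects (`geno`, `estimates`, `dapc`,
#'   `cv` data.frame, `deviance` tables, `manifest`) and the run
#'   directory in `$out_dir`
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(seed = config$seed, started = format(Sys.time()),
                   package_version = as.character(utils::packageVersion("clonalGS")),
                   files = character())
  add_file <- function(path) manifest$files <<- c(manifest$files, basename(path))
  out <- function(f) file.path(config$out_dir, f)

  # ingest or simulate
  if (is.null(config$genotype_path)) {
    simc <- config$sim
    simc$seed <- child_seed(config$seed, "simulate")
    geno_raw <- stage("simulate", simulate_structured_genotypes(simc))
    ph <- stage("simulate", simulate_phenotypes(geno_raw, simc))
    trials <- ph$trials
    truth <- ph$truth
  } else {
    fmt <- if (grepl("\\.vcf$", config$genotype_path)) "vcf" else "dosage_csv"
    geno_raw <- stage("ingest", read_genotypes(config$genotype_path, fmt))
    trials <- stage("ingest", utils::read.csv(config$phenotype_path,
                                              stringsAsFactors = FALSE))
    truth <- NULL
  }
  write_genotypes_csv(geno_raw, out("genotypes_raw.csv")); add_file("genotypes_raw.csv")
  utils::write.csv(trials, out("trials.csv"), row.names = FALSE); add_file("trials.csv")

  # stage 1 per trait
  estimates <- list()
  for (tr in config$traits) {
    est <- stage("pheno", deregress(fit_clonal_lmm(trials, tr)))
    estimates[[tr]] <- est
    cl <- est$clones
    utils::write.csv(cl, out(paste0("clonal_estimates_", tr, ".csv")),
                     row.names = FALSE)
    add_file(paste0("clonal_estimates_", tr, ".csv"))
  }
  jsonlite::write_json(lapply(estimates, function(e)
    c(as.list(e$varcomp), h2_phen = e$h2_phen)),
    out("variance_components.json"), auto_unbox = TRUE, digits = NA)
  add_file("variance_components.json")

  # marker QC and kernels
  geno <- stage("qc", qc_genotypes(geno_raw, config$min_call_rate, config$min_maf))
  jsonlite::write_json(attr(geno, "qc_report"), out("qc_report.json"),
                       auto_unbox = TRUE)
  add_file("qc_report.json")
  G <- stage("kernels", additive_G(geno))
  K <- stage("kernels", gaussian_K(geno))
  write_kinship_csv(G, out("kinship_G.csv")); add_file("kinship_G.csv")
  write_kinship_csv(K, out("kinship_K.csv")); add_file("kinship_K.csv")

  # structure
  dap <- stage("dapc", dapc_fit(geno, k = config$dapc_k,
                                pc_variance_threshold = config$pc_variance_threshold,
                                df_variance_threshold = config$df_variance_threshold,
                                seed = child_seed(config$seed, "dapc")))
  utils::write.csv(data.frame(id = names(dap$labels), cluster = dap$labels),
                   out("dapc_labels.csv"), row.names = FALSE)
  add_file("dapc_labels.csv")
  if (!is.null(dap$bic)) {
    utils::write.csv(dap$bic, out("dapc_bic.csv"), row.names = FALSE)
    add_file("dapc_bic.csv")
  }

  # cross-validation
  ids <- sample_ids(geno)
  cv_all <- list()
  for (strat in config$strategies) {
    plan <- stage("cv", make_cv_plan(strat, ids, dap$labels,
                                     replicates = config$cv_replicates,
                                     seed = child_seed(config$seed, "cv")))
    for (m in config$methods) for (tr in config$traits) {
      kern <- if (m == "gblup") G else if (m == "rkhs") K else NULL
      cv_all[[length(cv_all) + 1L]] <-
        stage("cv", run_cv(plan, m, geno, estimates[[tr]], trait = tr,
                           kernel = kern,
                           n_iter = config$n_iter, burn_in = config$burn_in,
                           thin = config$thin,
                           seed = child_seed(config$seed, "fit")))
    }
  }
  cv <- do.call(rbind, cv_all)
  utils::write.csv(cv, out("cv_metrics.csv"), row.names = FALSE)
  add_file("cv_metrics.csv")

  # method comparison per strategy
  devs <- list()
  if (length(config$methods) >= 2) {
    for (strat in unique(cv$strategy)) {
      sub <- cv[cv$strategy == strat, ]
      dv <- stage("compare",
                  deviance_analysis(sub, "predictive_ability",
                                    with_structure = !all(is.na(sub$validation_cluster))))
      devs[[strat]] <- dv
      utils::write.csv(dv$terms, out(paste0("deviance_", strat, ".csv")),
                       row.names = FALSE)
      utils::write.csv(dv$means, out(paste0("tukey_", strat, ".csv")),
                       row.names = FALSE)
      add_file(paste0("deviance_", strat, ".csv"))
      add_file(paste0("tukey_", strat, ".csv"))
    }
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(list(geno = geno, estimates = estimates, dapc = dap, cv = cv,
                 deviance = devs, truth = if (exists("truth")) truth else NULL,
                 manifest = manifest, out_dir = config$out_dir))
}
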
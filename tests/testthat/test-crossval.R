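test_that("S1 plans partition the panel into the requested folds", {
  ids <- sprintf("c%03d", 1:100)
  plan <- make_cv_plan("s1", ids, folds = 5, replicates = 3, seed = 2)
  expect_equal(length(plan$entries), 15)
  for (r in 1:3) {
    ent <- Filter(function(e) e$replicate == r, plan$entries)
    vals <- unlist(lapply(ent, `[[`, "validation_ids"))
    expect_setequal(vals, ids)
    expect_equal(anyDuplicated(vals), 0)
    for (e in ent) {
      expect_length(e$validation_ids, 20)
      expect_length(intersect(e$train_ids, e$validation_ids), 0)
      expect_setequal(c(e$train_ids, e$validation_ids), ids)
    }
  }
  plan2 <- make_cv_plan("s1", ids, folds = 5, replicates = 3, seed = 2)
  expect_identical(plan, plan2)
})

test_that("structured strategies respect their cluster constraints", {
  ids <- sprintf("c%03d", 1:100)
  lab <- setNames(rep(1:5, each = 20), ids)
  p2 <- make_cv_plan("s2", ids, lab, folds = 3, replicates = 2, seed = 3)
  expect_equal(length(p2$entries), 2 * 5 * 3)
  for (e in p2$entries)
    expect_equal(unique(lab[c(e$train_ids, e$validation_ids)]),
                 e$validation_cluster)

  p3 <- make_cv_plan("s3", ids, lab, folds = 3, replicates = 2, seed = 3)
  for (e in p3$entries) {
    expect_false(e$validation_cluster %in% lab[e$train_ids])
    expect_setequal(unique(lab[e$train_ids]), setdiff(1:5, e$validation_cluster))
  }
  p3f <- make_cv_plan("s3", ids, lab, folds = 3, replicates = 1, seed = 3,
                      full_training = TRUE)
  expect_equal(length(p3f$entries[[1]]$train_ids), 80)

  # S4: one extra absent cluster, every choice enumerated
  p4 <- make_cv_plan("s4", ids, lab, folds = 3, replicates = 1, seed = 3)
  expect_equal(length(p4$entries), 5 * 3 * 4)
  for (e in p4$entries) {
    expect_setequal(unique(lab[e$train_ids]),
                    setdiff(1:5, c(e$validation_cluster, e$absent_cluster)))
    expect_length(intersect(e$train_ids, e$validation_ids), 0)
  }
  expect_error(make_cv_plan("s4", ids, setNames(rep(1:2, each = 50), ids)),
               "at least 3")
  expect_error(make_cv_plan("s2", ids, lab, folds = 30), "smallest cluster")
  expect_error(make_cv_plan("s2", ids), "cluster labels")
})

test_that("fold metrics match their arithmetic oracles", {
  v <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  w <- c(0.9, -0.2, 0.8, 1.5, -0.7)
  expect_equal(predictive_ability(v, v), 1)
  expect_equal(predictive_ability(v, -v), -1)
  expect_equal(predictive_ability(v, w), cor(v, w))
  expect_warning(r0 <- predictive_ability(rep(1, 5), w), "zero variance")
  expect_true(is.na(r0))

  expect_equal(bias(v, v), 1)
  expect_equal(bias(v, 2 * v), 2)
  expect_equal(bias(v, w), cov(v, w) / var(v))
  expect_equal(bias(v, w, denominator = "sd"), cov(v, w) / sd(v))

  expect_equal(accuracy(0.5, 0.25), 1)
  expect_equal(accuracy(0, 0.3), 0)
  expect_equal(accuracy(0.4569, 0.337), 0.4569 / sqrt(0.337), tolerance = 1e-12)
  expect_equal(round(accuracy(0.4569, 0.337), 3), 0.787)
  expect_error(accuracy(0.5, 0), "h2_phen")
})

test_that("equivalent methods give equal fold metrics on a shared plan", {
  pan <- small_panel()
  plan <- make_cv_plan("s1", names(pan$yd), folds = 5, replicates = 1, seed = 5)
  G <- additive_G(pan$qc)
  cv_g <- run_cv(plan, "gblup", pan$qc, pan$est, kernel = G)
  cv_r <- run_cv(plan, "rrblup", pan$qc, pan$est)
  # same plan -> identical fold memberships -> near-identical metrics
  expect_equal(cv_g$n_train, cv_r$n_train)
  expect_equal(cv_g$n_val, cv_r$n_val)
  expect_equal(cv_g$predictive_ability, cv_r$predictive_ability, tolerance = 1e-6)
  expect_true(all(cv_g$accuracy == cv_g$predictive_ability /
                    sqrt(phenotypic_heritability(pan$est))))
})

test_that("near-noise-free traits reach high predictive ability", {
  # out-of-sample r is capped by sqrt(n_train / (n_train + M_e)), so the
  # signal-dominated limit needs training size large relative to markers
  cfg <- sim_config(n_clusters = 1, n_per_cluster = 250, fst = 0,
                    n_markers = 80, n_chromosomes = 1, missing_rate = 0,
                    n_qtl = 30, h2_additive = 0.95, nonadditive_fraction = 0,
                    trial_layouts = list(trial_layout("RCBD", 2, "loc1", 2013)),
                    seed = 55)
  g <- simulate_structured_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  est <- deregress(fit_clonal_lmm(ph$trials))
  plan <- make_cv_plan("s1", est$clones$clone, folds = 5, replicates = 1, seed = 6)
  cv <- run_cv(plan, "gblup", g, est)
  expect_gt(mean(cv$predictive_ability), 0.8)
})

test_that("random CV outperforms both structured designs on average", {
  res <- sapply(1:4, function(s) {
    cfg <- sim_config(n_clusters = 3, n_per_cluster = 60, fst = 0.30,
                      n_markers = 600, n_chromosomes = 3, missing_rate = 0,
                      n_qtl = 60, h2_additive = 0.4, nonadditive_fraction = 0,
                      trial_layouts = list(trial_layout("RCBD", 2, "loc1", 2013),
                                           trial_layout("RCBD", 2, "loc2", 2014)),
                      seed = 900 + s)
    g <- simulate_structured_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    est <- deregress(fit_clonal_lmm(ph$trials))
    lab <- ph$truth$cluster_labels
    G <- additive_G(g)
    ids <- est$clones$clone
    m_of <- function(cv) mean(cv$predictive_ability, na.rm = TRUE)
    c(s1 = m_of(run_cv(make_cv_plan("s1", ids, folds = 5, replicates = 1,
                                    seed = s), "gblup", g, est, kernel = G)),
      s2 = m_of(suppressWarnings(
        run_cv(make_cv_plan("s2", ids, lab, folds = 3, replicates = 1,
                            seed = s), "gblup", g, est, kernel = G))),
      s3 = m_of(suppressWarnings(
        run_cv(make_cv_plan("s3", ids, lab, folds = 3, replicates = 1,
                            seed = s), "gblup", g, est, kernel = G))))
  })
  means <- rowMeans(res)
  # the random design sees every cluster in training; both structured
  # designs lose that information (S2 vs S3 is not separable at this scale
  # with LD-free markers, so only the outer inequalities are asserted)
  expect_gt(means["s1"], means["s2"])
  expect_gt(means["s1"], means["s3"])
})

test_that("leave-cluster-out prediction pays for population structure", {
  pan <- small_panel()
  lab <- attr(pan$geno, "sim_truth")$cluster_labels
  G <- additive_G(pan$qc)
  s1 <- run_cv(make_cv_plan("s1", names(pan$yd), folds = 5, replicates = 1,
                            seed = 7), "gblup", pan$qc, pan$est, kernel = G)
  # tiny fold-part training sets can yield flat GEBVs in a fold; harmless here
  s3 <- suppressWarnings(
    run_cv(make_cv_plan("s3", names(pan$yd), lab, folds = 3,
                        replicates = 1, seed = 7),
           "gblup", pan$qc, pan$est, kernel = G))
  expect_lt(mean(s3$predictive_ability, na.rm = TRUE),
            mean(s1$predictive_ability, na.rm = TRUE))
})
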
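mk_geno <- function(dos, chrom = NULL) {
  dos <- as.matrix(dos)
  rownames(dos) <- paste0("s", seq_len(nrow(dos)))
  colnames(dos) <- paste0("m", seq_len(ncol(dos)))
  map <- if (is.null(chrom)) NULL else
    data.frame(marker = colnames(dos), chrom = chrom, pos = seq_len(ncol(dos)))
  genotype_matrix(dos, map)
}

test_that("call-rate filter counts observed calls against the threshold", {
  dos <- matrix(0, 10, 3)
  dos[1:2, 1] <- NA                # 8/10 observed
  dos[, 3] <- NA                   # all missing
  g <- mk_geno(dos)
  expect_equal(colnames(filter_call_rate(g, 0.90)$dosage), "m2")
  expect_setequal(colnames(filter_call_rate(g, 0.80)$dosage), c("m1", "m2"))
  # no missing data: identity
  g2 <- mk_geno(matrix(c(-1, 0, 1, 0), 4, 2))
  expect_identical(filter_call_rate(g2, 0.9)$dosage, g2$dosage)
})

test_that("naive imputation uses the marker mode with ties to heterozygote", {
  g <- mk_geno(cbind(c(1, 1, -1, NA), c(1, -1, NA, 0), c(0, 0, 1, -1)))
  out <- impute_naive(g)
  expect_equal(out$dosage[4, "m1"], 1)    # mode
  expect_equal(out$dosage[3, "m2"], 0)    # tie between 1 and -1 -> 0
  expect_identical(out$dosage[, "m3"], g$dosage[, "m3"])  # complete: identity
  g_all_na <- mk_geno(cbind(c(1, 1), c(NA, NA)))
  expect_error(impute_naive(g_all_na), "zero observed calls")
})

test_that("MAF filter removes monomorphic markers, boundary inclusive", {
  dos <- cbind(rep(-1, 10),                 # p = 0, monomorphic
               c(0, rep(-1, 9)),            # one het in 10: maf = 1/20 = 0.05
               c(rep(-1, 5), rep(1, 5)))    # p = 0.5
  g <- mk_geno(dos)
  out <- filter_maf(g, 0.05)
  expect_setequal(colnames(out$dosage), c("m2", "m3"))
  expect_error(filter_maf(mk_geno(cbind(c(NA, 1)))), "complete")
})

test_that("additive G matches the hand-computed VanRaden formula", {
  dos <- cbind(c(-1, 0, 1), c(1, 1, -1), c(0, 0, 0), c(-1, -1, 1))
  g <- mk_geno(dos)
  G <- additive_G(g, ridge = 0)
  p <- (colMeans(dos) + 1) / 2
  Zc <- sweep(dos, 2, 2 * (p - 0.5))
  denom <- 2 * sum(p * (1 - p))
  G_hand <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    G_hand[i, j] <- sum(Zc[i, ] * Zc[j, ]) / denom
  expect_equal(unclass(G), G_hand, ignore_attr = TRUE, tolerance = 1e-12)
  # uncentered variant is plain ZZ'/denom
  G_raw <- additive_G(g, center = FALSE, ridge = 0)
  expect_equal(unclass(G_raw), tcrossprod(dos) / denom,
               ignore_attr = TRUE, tolerance = 1e-12)
  # monomorphic-only input fails
  expect_error(additive_G(mk_geno(cbind(c(1, 1), c(-1, -1)))), "monomorphic")
})

test_that("clones have identical G rows and the diagonal behaves under HWE", {
  g <- panmictic_panel(n = 150, m = 600)
  dup <- genotype_matrix(rbind(g$dosage, dup1 = g$dosage[1, ]), g$map)
  G <- additive_G(dup)
  n <- nrow(G)
  expect_equal(unclass(G)[1, -c(1, n)], unclass(G)[n, -c(1, n)],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(G[1, n], G[1, 1] - 1e-6, tolerance = 1e-10)  # ridge only on diag
  expect_gt(mean(diag(G)), 0.9)
  expect_lt(mean(diag(G)), 1.1)
  # PSD after ridge
  expect_gte(min(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("gaussian K matches scalar hand computation and has unit diagonal", {
  dos <- cbind(c(-1, 0, 1), c(1, -1, 0), c(0, 1, -1))
  g <- mk_geno(dos)
  K <- gaussian_K(g, h = 1)
  D <- as.matrix(dist(dos))^2
  med <- median(D[upper.tri(D)])
  expect_equal(unclass(K), exp(-D / med), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(diag(unclass(K)), rep(1, 3), ignore_attr = TRUE)
  # identical rows give K entry 1
  g2 <- mk_geno(rbind(dos, dos[1, ]))
  expect_equal(unclass(gaussian_K(g2))[1, 4], 1)
  # all-identical individuals are degenerate
  expect_error(gaussian_K(mk_geno(rbind(c(1, 0), c(1, 0)))), "identical")
})

test_that("kernels are invariant to marker permutation and sign recoding", {
  g <- panmictic_panel(n = 40, m = 100)
  perm <- sample(100)
  gp <- genotype_matrix(g$dosage[, perm], g$map[perm, ])
  expect_equal(unclass(additive_G(g)), unclass(additive_G(gp)),
               tolerance = 1e-10, ignore_attr = TRUE)
  flip <- g$dosage
  flip[, 1:50] <- -flip[, 1:50]
  gf <- genotype_matrix(flip, g$map)
  expect_equal(unclass(gaussian_K(g)), unclass(gaussian_K(gf)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("QC pipeline order holds and output is sample-order invariant", {
  pan <- small_panel()
  g <- pan$geno
  out1 <- qc_genotypes(g)
  perm <- sample(nrow(g$dosage))
  gp <- genotype_matrix(g$dosage[perm, ], g$map)
  out2 <- qc_genotypes(gp)
  expect_setequal(colnames(out1$dosage), colnames(out2$dosage))
  expect_equal(out1$dosage[rownames(out2$dosage), ], out2$dosage)
  rep <- attr(out1, "qc_report")
  expect_equal(rep$call_rate$retained - rep$maf$removed, rep$maf$retained)
})

test_that("kernels from disjoint marker halves agree on structured data", {
  cfg <- sim_config(n_clusters = 3, n_per_cluster = 50, fst = 0.3,
                    n_markers = 2000, n_chromosomes = 2, missing_rate = 0,
                    n_qtl = 10, seed = 33)
  g <- simulate_structured_genotypes(cfg)
  half1 <- g[, seq(1, 2000, by = 2)]
  half2 <- g[, seq(2, 2000, by = 2)]
  for (fn in list(additive_G, gaussian_K)) {
    K1 <- unclass(fn(half1)); K2 <- unclass(fn(half2))
    expect_gt(cor(K1[upper.tri(K1)], K2[upper.tri(K2)]), 0.9)
  }
})

test_that("LD r2 behaves at its fixed points and under the null", {
  dos <- cbind(c(-1, 0, 1, 1, -1), c(-1, 0, 1, 1, -1), c(0, 1, -1, 0, 1))
  g <- mk_geno(dos, chrom = rep("1", 3))
  tab <- ld_r2(g, "1")
  expect_equal(tab$r2[tab$marker_a == "m1" & tab$marker_b == "m2"], 1)  # duplicate
  # null expectation: independent markers, E[r2] ~ 1/n
  set.seed(2)
  n <- 1000
  dosn <- matrix(rbinom(n * 40, 2, 0.5) - 1, n, 40)
  gn <- mk_geno(dosn, chrom = rep("1", 40))
  tabn <- ld_r2(gn, "1")
  expect_equal(mean(tabn$r2), 1 / n, tolerance = 0.5)
  # zero-variance marker skipped with warning
  gz <- mk_geno(cbind(c(1, 1, 1), c(-1, 0, 1)), chrom = rep("1", 2))
  expect_warning(ld_r2(gz, "1"), "zero-variance")
})

test_that("heterozygosity counts the dosage-0 fraction both ways", {
  g <- mk_geno(rbind(c(0, 0, 0, 0), c(-1, 0, 0, 1), c(-1, -1, 1, 1)))
  het <- heterozygosity(g)
  expect_equal(unname(het$individual), c(1, 0.5, 0))
  expect_equal(unname(het$marker), c(1, 2, 2, 1) / 3)
  # HWE at p = 0.5 gives Ho ~ 0.5
  gh <- panmictic_panel(n = 400, m = 100, seed = 77)
  p <- allele_freq(gh)
  ho <- heterozygosity(gh)$marker
  expect_equal(mean(ho), mean(2 * p * (1 - p)), tolerance = 0.05)
})
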
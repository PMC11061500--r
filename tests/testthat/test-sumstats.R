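test_that("allele frequencies handle missing calls by dropping copies", {
  ds <- toy_dataset(cbind(c(0L, 1L, 2L), c(2L, 2L, 2L), c(0L, 1L, NA)))
  af <- allele_freq(ds, "G1")
  expect_equal(af$freq, c(0.5, 1.0, 0.25))
  expect_equal(af$n_copies, c(6, 6, 4))
})

test_that("expected heterozygosity uses the unbiased estimator", {
  # p = 0.5 with n = 40 copies: 2 * 0.25 * 40/39
  dos <- matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1)
  ds <- toy_dataset(dos)
  he <- expected_heterozygosity(ds, "G1")
  expect_equal(he$mean_he, 0.5 * 40 / 39, tolerance = 1e-12)
  expect_equal(he$var_he, 0)             # single locus
  # fixed loci have zero heterozygosity
  ds0 <- toy_dataset(cbind(rep(0L, 5), rep(2L, 5)))
  expect_equal(expected_heterozygosity(ds0, "G1")$mean_he, 0)
})

test_that("Hudson FST is 1 at fixed differences and ~0 under identity", {
  g <- rep(c("A", "B"), each = 10)
  fixed <- toy_dataset(cbind(c(rep(0L, 10), rep(2L, 10)),
                             c(rep(2L, 10), rep(0L, 10))), groups = g)
  expect_equal(hudson_fst(fixed, "A", "B"), 1)
  # identical allele frequencies: estimator within its O(1/n) bias of zero
  g2 <- rep(c("A", "B"), each = 100)
  same <- toy_dataset(matrix(rep(c(0L, 1L, 2L, 1L, 0L), 40), nrow = 200,
                             byrow = FALSE), groups = g2)
  expect_lt(abs(hudson_fst(same, "A", "B")), 0.02)
})

test_that("Hudson FST matches an independent hand calculation", {
  # 3 loci, 2 groups of 3 diploids; brute-force arithmetic done separately
  dos <- cbind(c(0L, 1L, 2L, 2L, 2L, 1L),
               c(0L, 0L, 1L, 1L, 2L, 2L),
               c(1L, 1L, 1L, 0L, 0L, 0L))
  g <- rep(c("A", "B"), each = 3)
  ds <- toy_dataset(dos, groups = g)
  pa <- colSums(dos[1:3, ]) / 6
  pb <- colSums(dos[4:6, ]) / 6
  ha <- 2 * pa * (1 - pa) * 6 / 5
  hb_ <- 2 * pb * (1 - pb) * 6 / 5
  hw <- (ha + hb_) / 2
  hb <- pa * (1 - pb) + pb * (1 - pa)
  expect_equal(hudson_fst(ds, "A", "B"), 1 - mean(hw) / mean(hb),
               tolerance = 1e-12)
  # clipped reporting stays within [-0.1, 1]
  expect_gte(hudson_fst(same <- ds, "A", "B", clip = TRUE), -0.1)
})

test_that("Nei distance is 0 for identical frequencies and capped at log(0)", {
  g <- rep(c("A", "B"), each = 4)
  same <- toy_dataset(matrix(rep(c(0L, 1L, 2L, 1L), 2), nrow = 8,
                             byrow = FALSE, ncol = 2), groups = g)
  expect_equal(nei_distance(same, "A", "B"), 0, tolerance = 1e-12)
  opp <- toy_dataset(cbind(c(rep(0L, 4), rep(2L, 4))), groups = g)
  d <- nei_distance(opp, "A", "B", cap = 10)
  expect_equal(as.numeric(d), 10)
  expect_true(isTRUE(attr(d, "capped")))
})

test_that("Nei distance matches a two-locus hand computation", {
  g <- rep(c("A", "B"), each = 2)
  dos <- cbind(c(0L, 1L, 1L, 2L), c(2L, 2L, 1L, 1L))
  ds <- toy_dataset(dos, groups = g)
  pa <- colSums(dos[1:2, ]) / 4   # (0.25, 1.0)
  pb <- colSums(dos[3:4, ]) / 4   # (0.75, 0.5)
  jxy <- sum(pa * pb + (1 - pa) * (1 - pb))
  jx <- sum(pa^2 + (1 - pa)^2)
  jy <- sum(pb^2 + (1 - pb)^2)
  expect_equal(nei_distance(ds, "A", "B"), -log(jxy / sqrt(jx * jy)),
               tolerance = 1e-12)
})

test_that("f3 is negative for a perfectly intermediate target", {
  # target frequencies exactly midway between the sources at every locus,
  # large samples so the bias correction is negligible
  n <- 50
  dos <- rbind(
    matrix(rep(c(1L, 1L, 0L, 2L), each = n), nrow = n),      # target p=(.5,.5,0,1)
    matrix(rep(c(0L, 2L, 0L, 2L), each = n), nrow = n),      # source A
    matrix(rep(c(2L, 0L, 0L, 2L), each = n), nrow = n))      # source B
  ds <- toy_dataset(dos, groups = rep(c("T", "A", "B"), each = n))
  expect_lt(f3_stat(ds, "T", "A", "B"), 0)
})

test_that("f3 is non-negative on average for an unadmixed target", {
  # target and source A are independent samples of the same deme
  sc <- two_deme_split(3000, N = 500)
  set.seed(33)
  vals <- replicate(40, {
    ds <- simulate_snp_dataset(sc, sample_config(A = 12, B = 6), 60,
                               min_maf = 0.05)
    ids <- which(ds$individuals$group == "A")
    ds$individuals$group[ids[1:6]] <- "T"
    f3_stat(ds, "T", "A", "B")
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_gt(mean(vals), -3 * se)
})

test_that("f4 is centred on zero without gene flow across the quartet", {
  sc <- panmictic_scenario(N = 600)
  set.seed(34)
  vals <- replicate(40, {
    ds <- simulate_snp_dataset(sc, sample_config(POP = 12), 60, min_maf = 0.05)
    g <- rep(c("A", "B", "C", "D"), each = 3)
    ds$individuals$group <- g
    f4_stat(ds, "A", "B", "C", "D")
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("compute_summaries is pure, order-invariant and matches the parts", {
  sc <- two_deme_split(1500, N = 400)
  ds <- simulate_snp_dataset(sc, sample_config(A = 8, B = 8), 50,
                             min_maf = 0.05, seed = 35)
  before <- ds$dosages
  s1 <- compute_summaries(ds, groups = c("A", "B"))
  expect_identical(ds$dosages, before)             # no mutation
  expect_identical(s1, compute_summaries(ds, groups = c("A", "B")))
  # permuting loci leaves the vector unchanged
  perm <- sample(ncol(ds$dosages))
  ds_p <- snp_dataset(ds$dosages[, perm], ds$loci[perm, ], ds$individuals)
  expect_equal(compute_summaries(ds_p, groups = c("A", "B")), s1)
  # agreement with the individually exported statistics (dual route)
  expect_equal(unname(s1["fst_A.B"]), hudson_fst(ds, "A", "B"))
  expect_equal(unname(s1["nei_A.B"]), as.numeric(nei_distance(ds, "A", "B")))
  expect_equal(unname(s1["mean_he_A"]),
               expected_heterozygosity(ds, "A")$mean_he)
  expect_equal(names(s1), summary_header(c("A", "B")))
  expect_equal(attr(s1, "registry_version"), "hybridrf-ss-1")
})

test_that("the five-deme summary vector includes the admixture statistics", {
  pr <- prior_spec()
  pod <- make_pod(1, study_design("population", n_loci = 30),
                  theta = mid_prior_theta(1, pr), seed = 36)
  s <- compute_summaries(pod$dataset,
                         groups = c("PAM_N", "PAM_S", "HYB_N", "HYB_S", "HIM"))
  expect_true(all(c("f3_HYB_N", "f3_HYB_S", "f4_PAM.HYB_HIM") %in% names(s)))
  expect_equal(unname(s["f3_HYB_N"]),
               f3_stat(pod$dataset, "HYB_N", "PAM_N", "HIM"))
  expect_equal(unname(s["f4_PAM.HYB_HIM"]),
               f4_stat(pod$dataset, "PAM_N", "PAM_S", c("HYB_N", "HYB_S"),
                       "HIM"))
  # MAF-conditioned simulation: every locus polymorphic in the pooled sample
  expect_equal(unname(s["prop_poly_PAM_N"]) >= 0, TRUE)
  pooled <- colMeans(pod$dataset$dosages) / 2
  expect_true(all(pooled > 0 & pooled < 1))
})
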
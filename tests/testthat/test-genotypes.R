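test_that("DArT CSV round-trips and maps unknown symbols to missing", {
  ds <- toy_dataset(matrix(c(0L, 1L, 2L, 2L, NA, 0L), nrow = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dart_csv(ds, path)
  back <- read_dart_csv(path)
  expect_equal(dim(back), c(3, 2))
  expect_equal(unname(back$dosages), unname(ds$dosages))
  expect_equal(back$loci, ds$loci)

  # a dash call becomes missing, with a warning for the unrecognised symbol
  txt <- readLines(path)
  txt[2] <- sub(",0,", ",?,", txt[2])
  writeLines(txt, path)
  expect_warning(ds2 <- read_dart_csv(path), "mapped to missing")
  expect_equal(sum(is.na(ds2$dosages)), 2)
})

test_that("out-of-range dosage and malformed header are validation errors", {
  ds <- toy_dataset(matrix(c(0L, 1L, 2L, 0L), nrow = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dart_csv(ds, path)
  txt <- readLines(path)
  txt[2] <- sub("^(\"?L001\"?,[^,]*,[^,]*,[^,]*,[^,]*,)0", "\\13", txt[2])
  writeLines(txt, path)
  expect_error(read_dart_csv(path), "outside \\{0,1,2\\}",
               class = "hybridrf_validation_error")

  writeLines(sub("locus_id", "locus", readLines(path)[1]) |>
               c(readLines(path)[-1]), path)
  expect_error(read_dart_csv(path), "malformed header.*locus_id",
               class = "hybridrf_validation_error")
})

test_that("locus filters keep loci meeting both thresholds", {
  # call rates (1.0, 0.95, 1.0, 0.8, 1.0) over 20 individuals
  dos <- matrix(1L, nrow = 20, ncol = 5)
  dos[1, 2] <- NA
  dos[1:4, 4] <- NA
  ds <- toy_dataset(dos)
  expect_equal(n_loci(filter_loci(ds, 1, 1)), 3)
  expect_equal(n_loci(filter_loci(ds, 1, 0.95)), 4)
  expect_equal(n_loci(filter_loci(ds, 0, 0)), 5)   # identity
})

test_that("reproducibility filter combines with call rate", {
  dos <- matrix(1L, nrow = 4, ncol = 3)
  ds <- toy_dataset(dos, repro = c(1, 0.98, 1))
  expect_equal(filter_loci(ds, 1, 1)$loci$locus_id, c("L001", "L003"))
})

test_that("individual call-rate filter works and 0.895 boundary is inclusive", {
  dos <- matrix(0L, nrow = 3, ncol = 10)
  dos[2, 1] <- NA                       # individual 2: call rate 0.9
  ds <- toy_dataset(dos)
  expect_equal(n_individuals(filter_individuals(ds, 1)), 2)
  expect_equal(n_individuals(filter_individuals(ds, 0)), 3)
  # minimum individual call rate 0.895: threshold at that value keeps all
  dos2 <- matrix(0L, nrow = 5, ncol = 200)
  dos2[1, 1:21] <- NA                   # call rate 179/200 = 0.895
  ds2 <- toy_dataset(dos2)
  expect_equal(n_individuals(filter_individuals(ds2, 0.895)), 5)
  expect_equal(n_individuals(filter_individuals(ds2, 0.9)), 4)
})

test_that("monomorphic removal keeps only segregating loci", {
  dos <- cbind(c(0L, 0L, 0L), c(2L, 2L, 2L), c(0L, 0L, 1L),
               c(1L, 1L, 1L), c(0L, 2L, 1L), c(2L, 2L, NA))
  ds <- toy_dataset(dos)
  kept <- remove_monomorphic(ds)
  expect_equal(kept$loci$locus_id, c("L003", "L004", "L005"))
})

test_that("secondary-SNP thinning keeps one locus per clone, reproducibly", {
  dos <- matrix(1L, nrow = 2, ncol = 6)
  clone <- c("c1", "c1", "c1", "c2", "c3", "c3")  # group sizes 3, 1, 2
  ds <- toy_dataset(dos, clone = clone)
  thinned <- thin_secondary_snps(ds, seed = 42)
  expect_equal(n_loci(thinned), 3)
  expect_equal(sort(unique(thinned$loci$clone_id)), c("c1", "c2", "c3"))
  expect_identical(thin_secondary_snps(ds, seed = 42)$loci$locus_id,
                   thinned$loci$locus_id)
  # all-distinct clones: identity
  ds2 <- toy_dataset(dos)
  expect_identical(thin_secondary_snps(ds2, seed = 1)$loci$locus_id,
                   ds2$loci$locus_id)
})

test_that("group-polymorphism filter: strict and weak readings match brute force", {
  set.seed(7)
  dos <- matrix(sample(0:2, 10 * 10, replace = TRUE), nrow = 10)
  dos[, 1] <- c(rep(0L, 5), rep(1L, 5))   # fixed in G1, polymorphic in G2
  dos[, 2] <- 0L                          # fixed everywhere
  groups <- rep(c("G1", "G2"), each = 5)
  ds <- toy_dataset(dos, groups = groups)
  poly_in <- function(col, g) {
    v <- dos[groups == g, col]
    length(unique(v)) > 1 || any(v == 1)
  }
  expect_strict <- which(vapply(1:10, function(l)
    poly_in(l, "G1") && poly_in(l, "G2"), logical(1)))
  expect_weak <- which(vapply(1:10, function(l)
    poly_in(l, "G1") || poly_in(l, "G2"), logical(1)))
  gl <- list(G1 = "G1", G2 = "G2")
  expect_equal(filter_group_polymorphism(ds, gl, "strict")$loci$locus_id,
               ds$loci$locus_id[expect_strict])
  expect_equal(filter_group_polymorphism(ds, gl, "weak")$loci$locus_id,
               ds$loci$locus_id[expect_weak])
  expect_false(1 %in% match(filter_group_polymorphism(ds, gl, "strict")$loci$locus_id,
                            ds$loci$locus_id))
})

test_that("MAF filter threshold is inclusive", {
  # 20 diploids: alt count 1 of 40 copies (MAF 0.025) vs 2 of 40 (0.05)
  dos <- matrix(0L, nrow = 20, ncol = 3)
  dos[1, 1] <- 1L
  dos[1:2, 2] <- 1L
  dos[1:10, 3] <- 1L
  ds <- toy_dataset(dos)
  kept <- filter_maf(ds, 0.05)
  expect_equal(kept$loci$locus_id, c("L002", "L003"))
  expect_equal(n_loci(filter_maf(ds, 0)), 3)
})

test_that("filters are idempotent", {
  set.seed(11)
  dos <- matrix(sample(c(0:2, NA), 8 * 12, replace = TRUE,
                       prob = c(.4, .2, .3, .1)), nrow = 8)
  ds <- toy_dataset(dos, groups = rep(c("G1", "G2"), each = 4),
                    repro = runif(12, 0.9, 1))
  once <- filter_loci(ds, 0.95, 0.8)
  expect_identical(filter_loci(once, 0.95, 0.8)$loci, once$loci)
  once <- filter_maf(ds, 0.1)
  expect_identical(filter_maf(once, 0.1)$loci, once$loci)
  once <- remove_monomorphic(ds)
  expect_identical(remove_monomorphic(once)$loci, once$loci)
  once <- suppressWarnings(filter_individuals(ds, 0.9))
  expect_identical(suppressWarnings(filter_individuals(once, 0.9))$individuals,
                   once$individuals)
})

test_that("set_groups validates coverage", {
  ds <- toy_dataset(matrix(0:1, nrow = 2, ncol = 2))
  expect_error(set_groups(ds, tibble::tibble(individual_id = "i01",
                                             group_label = "A")),
               "no group label", class = "hybridrf_validation_error")
  ds2 <- set_groups(ds, tibble::tibble(individual_id = c("i01", "i02"),
                                       group_label = c("A", "B")))
  expect_equal(ds2$individuals$group, c("A", "B"))
})
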
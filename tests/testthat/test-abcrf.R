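test_that("reference tables are balanced, bounded and bit-identical by seed", {
  pr <- prior_spec()
  des <- study_design("population", n_loci = 15)
  expect_warning(
    tab <- build_reference_table(des, pr, n_per_scenario = 30, seed = 1),
    "recommended range")
  expect_equal(nrow(tab), 180)
  expect_equal(as.integer(table(tab$scenario_id)), rep(30L, 6))
  expect_warning(
    tab2 <- build_reference_table(des, pr, n_per_scenario = 30, seed = 1),
    "recommended range")
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # parameters respect their priors; unused parameters are NA per scenario
  expect_true(all(tab$t5 >= 1e5 & tab$t5 <= 2e5))
  expect_true(all(is.na(tab$t3[tab$scenario_id == 1])))
  expect_true(all(!is.na(tab$t3[tab$scenario_id == 2])))
  expect_true(all(is.na(tab$N_HYB_anc[tab$scenario_id <= 3])))
})

test_that("an alternative t5 upper bound propagates into the table", {
  pr <- prior_spec(t5_upper = 750000)
  des <- study_design("population", n_loci = 10)
  tab <- suppressWarnings(
    build_reference_table(des, pr, n_per_scenario = 10, seed = 2))
  expect_lte(max(tab$t5), 750000)
  expect_gt(max(tab$t5), 200000)   # draws actually use the wider range
})

test_that("reference tables persist with provenance", {
  tab <- separable_table(n_per_class = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
  expect_equal(attr(back, "stat_names"), attr(tab, "stat_names"))
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("the classifier separates separable scenarios almost perfectly", {
  tab <- separable_table(n_per_class = 150, shift = 5, seed = 2)
  fit <- fit_model_choice(tab, n_trees = 200, seed = 3)
  expect_lt(fit$prior_error_rate, 0.01)
  obs <- c(x1 = 0, x2 = 0, x3 = 0)       # class-1 centroid
  res <- classify_scenarios(fit, obs)
  expect_equal(res$selected, 1)
  expect_gt(res$votes$vote[res$votes$scenario_id == 1], 0.95)
  expect_gt(res$posterior_prob, 0.95)
  expect_equal(sum(res$votes$vote), 1, tolerance = 1e-9)
})

test_that("shuffled labels put the out-of-bag error at chance level", {
  tab <- separable_table(n_per_class = 150, shift = 5, seed = 4)
  set.seed(5)
  tab$scenario_id <- sample(tab$scenario_id)
  fit <- fit_model_choice(tab, n_trees = 200, seed = 5)
  expect_lt(abs(fit$prior_error_rate - 0.5), 0.1)   # 1 - 1/K, K = 2
})

test_that("indistinguishable scenarios split the votes evenly", {
  tab <- separable_table(n_per_class = 200, shift = 0, seed = 6)
  fit <- fit_model_choice(tab, n_trees = 300, seed = 7)
  res <- classify_scenarios(fit, c(x1 = 0, x2 = 0, x3 = 0))
  expect_true(all(res$votes$vote > 0.3 & res$votes$vote < 0.7))
})

test_that("classification is deterministic and checks the statistic header", {
  tab <- separable_table(n_per_class = 80, seed = 8)
  fit <- fit_model_choice(tab, n_trees = 100, seed = 9)
  obs <- c(x1 = 1, x2 = -1, x3 = 0)
  expect_identical(classify_scenarios(fit, obs)$votes,
                   classify_scenarios(fit, obs)$votes)
  expect_error(classify_scenarios(fit, c(x1 = 1, x2 = -1)),
               "lacks statistic", class = "hybridrf_validation_error")
})

test_that("quantile regression forests recover a planted relationship", {
  set.seed(10)
  n <- 400
  x1 <- runif(n, 0, 1)
  tab <- tibble::tibble(scenario_id = 1,
                        planted = 2 * x1,
                        noise = runif(n, 0, 1),
                        x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  attr(tab, "stat_names") <- c("x1", "x2", "x3")
  attr(tab, "param_names") <- c("planted", "noise")
  class(tab) <- c("reference_table", class(tab))
  obs <- c(x1 = 0.5, x2 = 0, x3 = 0)
  est <- estimate_parameters(tab, obs, 1, n_trees = 300, mtry = 3, seed = 11)
  pl <- est[est$parameter == "planted", ]
  expect_equal(pl$median, 1.0, tolerance = 0.1)
  expect_lt(pl$q95 - pl$q05, 0.3)          # informative: tight interval
  # a pure-noise parameter falls back to (approximately) its prior quantiles
  nz <- est[est$parameter == "noise", ]
  expect_gt(nz$median, 0.2)
  expect_lt(nz$median, 0.8)
  expect_lt(nz$q05, 0.2)
  expect_gt(nz$q95, 0.8)
  # quantile ordering always holds
  expect_true(all(est$q05 <= est$median & est$median <= est$q95))
})

test_that("replicated analyses summarise votes and subset mass", {
  tab <- separable_table(n_per_class = 120, seed = 12)
  tabs <- list(tab, separable_table(n_per_class = 120, seed = 13),
               separable_table(n_per_class = 120, seed = 14))
  obs <- c(x1 = 0, x2 = 0, x3 = 0)
  rs <- replicate_analysis(obs, design = NULL, prior = NULL,
                           n_per_scenario = NA, n_replicates = 3,
                           n_trees = 100, seed = 15, estimate_params = FALSE,
                           combine = list(1, c(1, 2)), ref_tables = tabs)
  expect_equal(rs$selected, 1)
  expect_equal(nrow(rs$vote_summary), 2)
  expect_lt(rs$vote_summary$sd_vote[1], 0.02)   # separable: stable votes
  expect_equal(rs$subset_summary$mean_vote[rs$subset_summary$subset == "1+2"],
               1, tolerance = 1e-9)
  expect_true(all(rs$vote_summary$mean_vote >= 0))
  # same seed, same tables: identical rerun
  rs2 <- replicate_analysis(obs, design = NULL, prior = NULL,
                            n_per_scenario = NA, n_replicates = 3,
                            n_trees = 100, seed = 15, estimate_params = FALSE,
                            combine = list(1, c(1, 2)), ref_tables = tabs)
  expect_identical(rs$vote_summary, rs2$vote_summary)
  expect_identical(rs$posterior_mean, rs2$posterior_mean)
})

test_that("a single replicate yields NA spread with a warning", {
  tab <- separable_table(n_per_class = 60, seed = 16)
  expect_warning(
    rs <- replicate_analysis(c(x1 = 0, x2 = 0, x3 = 0), design = NULL,
                             prior = NULL, n_per_scenario = NA,
                             n_replicates = 1, n_trees = 50, seed = 17,
                             estimate_params = FALSE, combine = list(),
                             ref_tables = list(tab)),
    "single replicate")
  expect_true(is.na(rs$posterior_sd))
  expect_true(all(is.na(rs$vote_summary$sd_vote)))
})

test_that("tidy and glance expose votes and headline numbers", {
  tab <- separable_table(n_per_class = 60, seed = 18)
  fit <- fit_model_choice(tab, n_trees = 100, seed = 19)
  res <- classify_scenarios(fit, c(x1 = 0, x2 = 0, x3 = 0))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("scenario_id", "vote"))
  gl <- glance(res)
  expect_named(gl, c("selected", "posterior_prob", "prior_error_rate"))
  expect_true(gl$posterior_prob >= 0 && gl$posterior_prob <= 1)
  expect_true(gl$prior_error_rate >= 0 && gl$prior_error_rate <= 1)
})
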
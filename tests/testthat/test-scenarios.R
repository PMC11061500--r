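test_that("parameter draws respect prior ranges and ordering constraints", {
  pr <- prior_spec()
  for (seed in 1:20) {
    th1 <- draw_parameters(pr, 1, seed = seed)
    expect_lt(th1$times["t1"], th1$times["t2"])
    expect_true(all(th1$times[c("t1", "t2")] >= 10 &
                      th1$times[c("t1", "t2")] <= 25000))
    th5 <- draw_parameters(pr, 5, seed = seed)
    expect_lt(th5$times["t3"], th5$times["t4"])
    expect_true(all(th5$times[c("t3", "t4")] >= 25000 &
                      th5$times[c("t3", "t4")] <= 50000))
  }
  expect_identical(draw_parameters(pr, 3, seed = 9),
                   draw_parameters(pr, 3, seed = 9))
})

test_that("r1 draws are uniform on [0.01, 0.99]", {
  pr <- prior_spec()
  r1 <- with(list(), {
    set.seed(123)
    replicate(10000, draw_parameters(pr, 4)$r1)
  })
  expect_gte(min(r1), 0.01)
  expect_lte(max(r1), 0.99)
  se <- sqrt(var(r1) / length(r1))
  expect_lt(abs(mean(r1) - 0.5), 3 * se)
})

test_that("multi-event scenarios place two admixtures before the PAM split", {
  pr <- prior_spec()
  th <- mid_prior_theta(1, pr)
  th$times <- c(t1 = 5000, t2 = 20000, t5 = 150000)
  sc <- build_scenario(1, th, pr)
  expect_equal(nrow(sc$events), 4)
  expect_equal(sc$events$kind, c("admixture", "admixture", "merge", "merge"))
  expect_true(all(diff(sc$events$time) >= 0))
  expect_equal(scenario_origin_class(sc), "multi-event")
  # both admixtures share r1 and draw from the matching PAM deme
  adm <- sc$events[sc$events$kind == "admixture", ]
  expect_equal(adm$frac_a, c(0.5, 0.5))
  expect_equal(adm$parent_a, c("PAM_N", "PAM_S"))
  expect_equal(adm$parent_b, c("HIM", "HIM"))
})

test_that("single-event scenarios merge hybrid lineages before the admixture", {
  pr <- prior_spec()
  th <- mid_prior_theta(4, pr)
  th$times <- c(t1 = 1000, t2 = 20000, t5 = 150000)
  sc <- build_scenario(4, th, pr)
  expect_equal(sc$events$kind, c("merge", "merge", "admixture", "merge"))
  expect_equal(sc$events$child[1], "HYB_S")   # HYB_anc forms first (backward)
  expect_lt(sc$events$time[1], sc$events$time[3])
  expect_equal(scenario_origin_class(sc), "single-event")
})

test_that("times outside the prior support are rejected", {
  pr <- prior_spec()
  th <- mid_prior_theta(3, pr)
  th$times["t2"] <- 30000      # t2 must lie in [10, 25000]
  expect_error(build_scenario(3, th, pr), "outside its prior range",
               class = "hybridrf_validation_error")
  th2 <- mid_prior_theta(1, pr)
  th2$times["t1"] <- 20000; th2$times["t2"] <- 10000
  expect_error(build_scenario(1, th2, pr), "t1 < t2",
               class = "hybridrf_validation_error")
})

test_that("every scenario reduces to a single ancestral deme for random draws", {
  pr <- prior_spec()
  for (sc_id in 1:6) {
    for (seed in 1:5) {
      th <- draw_parameters(pr, sc_id, seed = 100 * sc_id + seed)
      sc <- build_scenario(sc_id, th, pr)   # constructor runs occupancy check
      expect_s3_class(sc, "demographic_scenario")
      expect_equal(scenario_origin_class(sc),
                   if (sc_id <= 3) "multi-event" else "single-event")
    }
  }
})

test_that("invalid event lists are rejected", {
  expect_error(two_deme_split(-5), "positive",
               class = "hybridrf_validation_error")
  # dangling second deme: events never merge it
  ev <- tibble::tibble(time = 10, kind = "merge", child = "B", parent_a = "A",
                       parent_b = NA, frac_a = NA, new_size = 100)
  expect_error(demographic_scenario(ev, sizes = c(A = 10, B = 10, C = 10)),
               "unmerged", class = "hybridrf_validation_error")
})

test_that("generation-time conversion multiplies by 2 years by default", {
  th <- list(times = c(t1 = 25000), generation_time_years = 2)
  expect_equal(unname(generations_to_years(th)), 50000)
  expect_equal(unname(generations_to_years(list(times = c(t1 = 0),
                                                generation_time_years = 2))), 0)
  # a 150-5500 generation window maps onto the ~300-11,000 year range
  th2 <- list(times = c(lo = 150, hi = 5500), generation_time_years = 2)
  expect_equal(unname(generations_to_years(th2)), c(300, 11000))
  expect_equal(unname(generations_to_years(th, generation_time_years = 1)),
               25000)
})

test_that("prior configuration round-trips through YAML", {
  pr <- prior_spec(t5_upper = 750000, n_range = c(100, 50000),
                   r1_range = c(0.05, 0.95), generation_time_years = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_prior_config(pr, path)
  back <- read_prior_config(path)
  expect_equal(back, pr)
})

test_that("prior validation rejects unsupported settings", {
  expect_error(prior_spec(t5_upper = 300000), "t5_upper",
               class = "hybridrf_validation_error")
  expect_error(prior_spec(n_range = c(0, 10)), "n_range",
               class = "hybridrf_validation_error")
  expect_error(prior_spec(r1_range = c(0, 0.99)), "r1_range",
               class = "hybridrf_validation_error")
})
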
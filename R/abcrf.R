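#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per scenario, each matching the
#' observed study design (sample sizes, locus count, MAF ascertainment):
#' draw a parameter vector from the prior, simulate the SNP dataset, compute
#' the summary vector. Rows carry the scenario label, the drawn parameters
#' (NA for parameters the scenario does not use) and the summary statistics.
#' Parameter draws for which the simulator's per-locus rejection cap is
#' exhausted are resampled (the count is recorded in the provenance).
#'
#' The recommended range for model choice is 2,000-20,000 simulations per
#' scenario; values outside it trigger a warning only. Seeds are derived
#' deterministically per scenario and draw from `seed`, so any row is
#' independently reproducible and the full table is bit-identical under a
#' fixed seed.
#'
#' @param design a [study_design()].
#' @param prior a [prior_spec()].
#' @param n_per_scenario simulations per scenario.
#' @param scenario_ids scenarios to include (default 1:6).
#' @param seed master integer seed.
#' @param max_attempts per-locus rejection cap passed to the simulator.
#' @return a `reference_table`: tibble with columns `scenario_id`, the
#'   parameter columns and the summary statistics; attributes `provenance`
#'   and `stat_names`.
#' @export
build_reference_table <- function(design, prior, n_per_scenario,
                                  scenario_ids = 1:6, seed = 1,
                                  max_attempts = 10000) {
  stopifnot(inherits(design, "study_design"), inherits(prior, "prior_spec"))
  if (n_per_scenario < 2000 || n_per_scenario > 20000)
    warn(sprintf(
      "n_per_scenario = %d outside the recommended range [2000, 20000]",
      n_per_scenario))
  groups <- names(design$samples)
  all_lineages <- unique(unlist(lapply(scenario_ids, scenario_lineages)))
  time_syms <- paste0("t", 1:5)
  n_resampled <- 0L
  rows <- vector("list", length(scenario_ids) * n_per_scenario)
  k <- 0L
  gidx <- split(seq_len(sum(design$samples)),
                rep(groups, times = design$samples))[groups]
  for (sc in scenario_ids) {
    for (i in seq_len(n_per_scenario)) {
      row_seed <- derive_seed(seed, sc * 1000003L + i)
      sim <- NULL
      for (try in 1:50) {
        sim <- tryCatch({
          with_seed(derive_seed(row_seed, try), {
            theta <- draw_parameters(prior, sc)
            scen <- build_scenario(sc, theta, prior)
            ds <- simulate_snp_dataset(scen, design$samples, design$n_loci,
                                       min_maf = design$min_maf,
                                       max_attempts = max_attempts)
            list(theta = theta, ds = ds)
          })
        }, hybridrf_runtime_error = function(e) NULL)
        if (!is.null(sim)) break
        n_resampled <- n_resampled + 1L
      }
      if (is.null(sim))
        stop_runtime("scenario %d: 50 consecutive parameter draws hit the simulator cap", sc)
      stats <- summaries_core(sim$ds$dosages, gidx)
      pv <- setNames(rep(NA_real_, length(time_syms) + 1 + length(all_lineages)),
                     c(time_syms, "r1", paste0("N_", all_lineages)))
      pv[names(sim$theta$times)] <- sim$theta$times
      pv["r1"] <- sim$theta$r1
      pv[paste0("N_", names(sim$theta$N))] <- sim$theta$N
      k <- k + 1L
      rows[[k]] <- c(scenario_id = sc, pv, stats)
    }
  }
  tab <- as_tibble(as.data.frame(do.call(rbind, rows)))
  stat_names <- setdiff(names(tab),
                        c("scenario_id", time_syms, "r1",
                          paste0("N_", all_lineages)))
  attr(tab, "stat_names") <- stat_names
  attr(tab, "param_names") <- c(time_syms, "r1", paste0("N_", all_lineages))
  attr(tab, "provenance") <- list(
    seed = seed, n_per_scenario = n_per_scenario,
    scenario_ids = scenario_ids, design = design$name,
    n_loci = design$n_loci, min_maf = design$min_maf,
    samples = as.list(design$samples),
    prior_t5_upper = prior$t5[2], prior_n_range = prior$N,
    n_resampled_draws = n_resampled,
    registry_version = SUMMARY_REGISTRY_VERSION)
  class(tab) <- c("reference_table", class(tab))
  tab
}

#' Persist / load a reference table
#'
#' CSV for the rows plus a JSON sidecar (`<path>.json`) for the provenance.
#'
#' @param tab a `reference_table`.
#' @param path CSV path.
#' @return `path` (write) / a `reference_table` (read).
#' @export
write_reference_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  meta <- attributes(tab)[c("stat_names", "param_names", "provenance")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  tab <- as_tibble(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(tab, "stat_names") <- meta$stat_names
  attr(tab, "param_names") <- meta$param_names
  attr(tab, "provenance") <- meta$provenance
  class(tab) <- c("reference_table", class(tab))
  tab
}

ref_features <- function(tab) {
  sn <- attr(tab, "stat_names")
  if (is.null(sn)) stop_validation("not a reference table (missing stat_names)")
  as.data.frame(tab[, sn, drop = FALSE])
}

#' Fit the random-forest scenario classifier
#'
#' Trains a classification random forest on the summary-statistic columns of
#' a reference table. Optionally (default) the linear-discriminant
#' projections of the summaries (up to K-1 axes for K scenarios, fitted on
#' the reference table only) are appended as extra features, following
#' common ABC-RF practice. A second, regression forest is trained on the
#' out-of-bag misclassification indicator; it provides the posterior
#' probability of the selected scenario at the observed point
#' (`1 - predicted error`).
#'
#' @param tab a `reference_table`.
#' @param n_trees number of trees (default 500).
#' @param add_lda append linear-discriminant axes as features.
#' @param seed integer seed for both forests.
#' @return a `model_choice_fit`.
#' @export
fit_model_choice <- function(tab, n_trees = 500, add_lda = TRUE, seed = 1) {
  X <- ref_features(tab)
  y <- factor(tab$scenario_id)
  keep <- vapply(X, function(col) stats::sd(col) > 0 && all(is.finite(col)),
                 logical(1))
  X <- X[, keep, drop = FALSE]
  lda_fit <- NULL
  if (add_lda && nlevels(y) > 1) {
    lda_fit <- tryCatch(suppressWarnings(MASS::lda(X, grouping = y)),
                        error = function(e) NULL)
    if (!is.null(lda_fit)) {
      proj <- as.data.frame(predict(lda_fit, X)$x)
      names(proj) <- paste0("LDA", seq_along(proj))
      X <- cbind(X, proj)
    }
  }
  rf <- ranger::ranger(x = X, y = y, num.trees = n_trees, seed = seed,
                       num.threads = 1)
  oob_err <- as.integer(rf$predictions != y)
  err_rf <- ranger::ranger(x = X, y = oob_err, num.trees = n_trees,
                           seed = seed + 1L, num.threads = 1)
  structure(list(rf = rf, err_rf = err_rf, lda = lda_fit,
                 feature_names = names(X),
                 stat_names = colnames(ref_features(tab))[keep],
                 levels = levels(y),
                 prior_error_rate = mean(oob_err),
                 n_trees = n_trees,
                 registry_version = attr(tab, "provenance")$registry_version),
            class = "model_choice_fit")
}

#' @export
print.model_choice_fit <- function(x, ...) {
  cat(sprintf("<model_choice_fit> %d scenarios, %d trees, %d features; prior error rate %.3f\n",
              length(x$levels), x$n_trees, length(x$feature_names),
              x$prior_error_rate))
  invisible(x)
}

observed_features <- function(fit, observed) {
  if (is.list(observed) && !is.data.frame(observed)) observed <- unlist(observed)
  miss <- setdiff(fit$stat_names, names(observed))
  if (length(miss) > 0)
    stop_validation("observed summary vector lacks statistic(s): %s",
                    paste(head(miss, 5), collapse = ", "))
  X <- as.data.frame(as.list(observed[fit$stat_names]))
  names(X) <- fit$stat_names
  if (!is.null(fit$lda)) {
    proj <- as.data.frame(predict(fit$lda, X)$x)
    names(proj) <- paste0("LDA", seq_along(proj))
    X <- cbind(X, proj)
  }
  X
}

#' Scenario choice for an observed summary vector
#'
#' Vote fractions are the proportions of trees voting for each scenario; the
#' selected scenario is the plurality winner. The posterior probability of
#' that choice is estimated as `1 -` the error predicted by the out-of-bag
#' error-regression forest at the observed point.
#'
#' @param fit a `model_choice_fit`.
#' @param observed named numeric summary vector (same statistic registry as
#'   the reference table; a header mismatch is a hard error).
#' @return a `model_choice_result` with `votes` (tibble `scenario_id`,
#'   `vote`), `selected`, `posterior_prob`, `prior_error_rate`.
#' @export
classify_scenarios <- function(fit, observed) {
  stopifnot(inherits(fit, "model_choice_fit"))
  X <- observed_features(fit, observed)
  pred <- predict(fit$rf, data = X, predict.all = TRUE, num.threads = 1)
  counts <- tabulate(pred$predictions[1, ], nbins = length(fit$levels))
  votes <- counts / sum(counts)
  perr <- predict(fit$err_rf, data = X, num.threads = 1)$predictions
  structure(list(
    votes = tibble(scenario_id = as.integer(fit$levels), vote = votes),
    selected = as.integer(fit$levels[which.max(votes)]),
    posterior_prob = min(max(1 - perr, 0), 1),
    prior_error_rate = fit$prior_error_rate),
    class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat(sprintf("<model_choice_result> selected scenario %d (posterior prob. %.3f, prior error rate %.3f)\n",
              x$selected, x$posterior_prob, x$prior_error_rate))
  v <- x$votes[order(-x$votes$vote), ]
  cat(paste(sprintf("  S%d: %.1f%%", v$scenario_id, 100 * v$vote),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.model_choice_result <- function(x, ...) x$votes

#' @export
glance.model_choice_result <- function(x, ...) {
  tibble(selected = x$selected, posterior_prob = x$posterior_prob,
         prior_error_rate = x$prior_error_rate)
}

#' Quantile-regression-forest parameter estimation
#'
#' For each parameter, a quantile regression forest is trained on the
#' reference-table rows of the selected scenario (parameter ~ summary
#' statistics); the posterior distribution at the observed point is the
#' training responses weighted by leaf co-occurrence with the observation,
#' summarised by its weighted median and 5% / 95% quantiles.
#'
#' @param tab a `reference_table`.
#' @param observed named numeric summary vector.
#' @param scenario_id scenario whose rows to train on (typically the
#'   selected one).
#' @param params parameters to estimate; default: all parameters the
#'   scenario uses (non-constant, non-NA columns).
#' @param n_trees trees per forest.
#' @param mtry candidate features per split; default one third of the
#'   features (the usual quantile-regression-forest setting).
#' @param seed integer seed.
#' @return a `param_posterior` tibble: `parameter`, `q05`, `median`, `q95`.
#' @export
estimate_parameters <- function(tab, observed, scenario_id, params = NULL,
                                n_trees = 500, mtry = NULL, seed = 1) {
  sub <- tab[tab$scenario_id == scenario_id, , drop = FALSE]
  if (nrow(sub) < 10)
    stop_validation("only %d reference rows for scenario %s", nrow(sub),
                    scenario_id)
  if (is.null(params)) {
    pn <- attr(tab, "param_names")
    ok <- vapply(pn, function(p) {
      v <- sub[[p]]
      !anyNA(v) && stats::sd(v) > 0
    }, logical(1))
    params <- pn[ok]
  }
  sn <- attr(tab, "stat_names")
  Xtr <- as.data.frame(sub[, sn, drop = FALSE])
  keep <- vapply(Xtr, function(col) stats::sd(col) > 0 && all(is.finite(col)),
                 logical(1))
  Xtr <- Xtr[, keep, drop = FALSE]
  miss <- setdiff(names(Xtr), names(observed))
  if (length(miss) > 0)
    stop_validation("observed summary vector lacks statistic(s): %s",
                    paste(head(miss, 5), collapse = ", "))
  Xobs <- as.data.frame(as.list(unlist(observed)[names(Xtr)]))
  names(Xobs) <- names(Xtr)
  if (is.null(mtry)) mtry <- max(1, floor(ncol(Xtr) / 3))
  out <- purrr::map_dfr(seq_along(params), function(i) {
    p <- params[i]
    # quantreg forests also draw from R's global RNG when sampling terminal
    # node values, so pin that stream too for bit-identical reruns
    qrf <- with_seed(seed + i,
      ranger::ranger(x = Xtr, y = sub[[p]], num.trees = n_trees,
                     quantreg = TRUE, mtry = mtry, seed = seed + i,
                     num.threads = 1))
    q <- predict(qrf, data = Xobs, type = "quantiles",
                 quantiles = c(0.05, 0.5, 0.95), num.threads = 1)$predictions
    tibble(parameter = p, q05 = q[1], median = q[2], q95 = q[3])
  })
  class(out) <- c("param_posterior", class(out))
  out
}

#' Replicated ABC-RF analysis
#'
#' Runs `R` full repetitions of the pipeline — an independent reference
#' table, scenario classifier and (optionally) parameter estimation each
#' time, with per-replicate seeds derived from the master seed — and
#' summarises vote fractions and the posterior probability of the winning
#' scenario as mean and SD over replicates. Vote mass can additionally be
#' combined over arbitrary scenario subsets (e.g. the two multi-event
#' scenarios).
#'
#' @param observed named numeric summary vector of the observed dataset.
#' @param design a [study_design()] the simulations must match.
#' @param prior a [prior_spec()].
#' @param n_per_scenario simulations per scenario per replicate.
#' @param n_replicates number of replicate analyses (`R`); with `R = 1` the
#'   SD columns are `NA` and a warning is raised.
#' @param n_trees trees per forest.
#' @param scenario_ids scenarios to compare.
#' @param seed master integer seed.
#' @param add_lda append LDA axes as classifier features.
#' @param estimate_params estimate parameters under the overall winning
#'   scenario in every replicate.
#' @param combine list of integer vectors: scenario subsets whose vote mass
#'   and posterior support to report jointly.
#' @param ref_tables optional pre-built list of reference tables (length
#'   `n_replicates`), e.g. to reuse tables across calls.
#' @return a `replicate_summary`.
#' @export
replicate_analysis <- function(observed, design, prior, n_per_scenario,
                               n_replicates = 10, n_trees = 500,
                               scenario_ids = 1:6, seed = 1, add_lda = TRUE,
                               estimate_params = TRUE,
                               combine = list(c(1, 3)), ref_tables = NULL) {
  if (n_replicates < 1) stop_validation("n_replicates must be >= 1")
  if (n_replicates == 1) warn("single replicate: SD columns will be NA")
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rseed <- derive_seed(seed, r)
    tab <- if (!is.null(ref_tables)) ref_tables[[r]] else
      suppressWarnings(build_reference_table(design, prior, n_per_scenario,
                                             scenario_ids, seed = rseed))
    fit <- fit_model_choice(tab, n_trees = n_trees, add_lda = add_lda,
                            seed = rseed)
    res <- classify_scenarios(fit, observed)
    reps[[r]] <- list(table = tab, fit = fit, result = res)
  }
  votes <- do.call(rbind, lapply(reps, function(x) x$result$votes$vote))
  colnames(votes) <- reps[[1]]$result$votes$scenario_id
  sd_or_na <- function(x) if (length(x) > 1) sd(x) else NA_real_
  vote_summary <- tibble(
    scenario_id = as.integer(colnames(votes)),
    mean_vote = colMeans(votes),
    sd_vote = apply(votes, 2, sd_or_na))
  selected <- vote_summary$scenario_id[which.max(vote_summary$mean_vote)]
  post <- vapply(reps, function(x) x$result$posterior_prob, numeric(1))
  subset_summary <- purrr::map_dfr(combine, function(s) {
    mass <- rowSums(votes[, as.character(s), drop = FALSE])
    tibble(subset = paste(s, collapse = "+"),
           mean_vote = mean(mass), sd_vote = sd_or_na(mass))
  })
  params <- NULL
  if (estimate_params) {
    per_rep <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      est <- estimate_parameters(reps[[r]]$table, observed, selected,
                                 n_trees = n_trees,
                                 seed = derive_seed(seed, 10000L + r))
      est$replicate <- r
      est
    })
    params <- dplyr::summarise(
      dplyr::group_by(per_rep, .data$parameter),
      q05 = mean(.data$q05), median = mean(.data$median),
      q95 = mean(.data$q95), .groups = "drop")
    class(params) <- c("param_posterior", class(params))
  }
  structure(list(vote_summary = vote_summary, selected = selected,
                 posterior_mean = mean(post), posterior_sd = sd_or_na(post),
                 prior_error_rate = mean(vapply(reps, function(x)
                   x$result$prior_error_rate, numeric(1))),
                 subset_summary = subset_summary, params = params,
                 n_replicates = n_replicates, seed = seed,
                 per_replicate_votes = votes),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %d replicates; selected scenario %d\n",
              x$n_replicates, x$selected))
  v <- x$vote_summary[order(-x$vote_summary$mean_vote), ]
  cat(paste(sprintf("  S%d: %.1f +- %.1f%%", v$scenario_id, 100 * v$mean_vote,
                    100 * v$sd_vote), collapse = "\n"), "\n")
  cat(sprintf("posterior probability %.3f +- %.3f\n", x$posterior_mean,
              x$posterior_sd))
  invisible(x)
}

#' @export
tidy.replicate_summary <- function(x, ...) x$vote_summary

#' @export
glance.replicate_summary <- function(x, ...) {
  tibble(selected = x$selected, posterior_mean = x$posterior_mean,
         posterior_sd = x$posterior_sd,
         prior_error_rate = x$prior_error_rate,
         n_replicates = x$n_replicates)
}
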
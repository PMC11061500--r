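#' Run the full SNP filtering cascade
#'
#' Applies the filters in the conventional order — locus reproducibility and
#' call rate, individual call rate, monomorphic removal, secondary-SNP
#' thinning, group-polymorphism filter, pooled MAF — recomputing call rates
#' on the surviving matrix at each step, and returns a per-step retention
#' report. Only the thinning step consumes randomness, so changing the seed
#' alters nothing else.
#'
#' @param ds a [snp_dataset()].
#' @param min_reproducibility,min_locus_call_rate,min_individual_call_rate
#'   quality thresholds in `[0, 1]`.
#' @param polymorphic_groups named list of group-label vectors for
#'   [filter_group_polymorphism()]; `NULL` skips the step.
#' @param polymorphism_mode `"strict"` or `"weak"`.
#' @param min_maf pooled MAF threshold; `NULL` skips the step.
#' @param seed integer seed for the thinning step.
#' @return list with `dataset` (the filtered [snp_dataset()]) and `report`
#'   (tibble: step, retained loci and individuals).
#' @export
run_filter_cascade <- function(ds, min_reproducibility = 1,
                               min_locus_call_rate = 1,
                               min_individual_call_rate = 1,
                               polymorphic_groups = NULL,
                               polymorphism_mode = "strict",
                               min_maf = 0.05, seed = NULL) {
  steps <- list()
  note <- function(step, d) {
    steps[[length(steps) + 1]] <<- tibble(step = step,
                                          retained_loci = ncol(d$dosages),
                                          retained_individuals = nrow(d$dosages))
    d
  }
  ds <- note("input", ds)
  ds <- note("locus_quality",
             filter_loci(ds, min_reproducibility, min_locus_call_rate))
  ds <- note("individual_callrate",
             filter_individuals(ds, min_individual_call_rate))
  ds <- note("monomorphic", remove_monomorphic(ds))
  ds <- note("thin_secondary", thin_secondary_snps(ds, seed = seed))
  if (!is.null(polymorphic_groups))
    ds <- note("group_polymorphism",
               filter_group_polymorphism(ds, polymorphic_groups,
                                         mode = polymorphism_mode))
  else ds <- note("group_polymorphism", ds)
  if (!is.null(min_maf)) ds <- note("maf", filter_maf(ds, min_maf))
  else ds <- note("maf", ds)
  list(dataset = ds, report = dplyr::bind_rows(steps))
}

#' End-to-end demographic inference on an observed dataset
#'
#' Computes the observed summary vector, runs the replicated ABC-RF analysis
#' (independent reference tables, scenario classification, parameter
#' estimation under the winning scenario) and converts the winning
#' scenario's time estimates to calendar years with the configured
#' generation time. Every output embeds the master seed and enough
#' configuration to reproduce it bit-identically.
#'
#' @param ds a filtered [snp_dataset()] whose groups match the design demes.
#' @param design a [study_design()].
#' @param prior a [prior_spec()].
#' @param n_per_scenario simulations per scenario per replicate.
#' @param n_replicates replicate analyses.
#' @param n_trees trees per forest.
#' @param seed master integer seed.
#' @param ... further arguments passed to [replicate_analysis()].
#' @return an `inference_result`: list with `summary` (a
#'   `replicate_summary`), `observed_stats`, `params_years` (time posteriors
#'   in years) and `provenance`.
#' @export
run_inference <- function(ds, design, prior = prior_spec(),
                          n_per_scenario = 2000, n_replicates = 10,
                          n_trees = 500, seed = 1, ...) {
  groups <- names(design$samples)
  observed <- compute_summaries(ds, groups = groups)
  summary <- replicate_analysis(observed, design, prior, n_per_scenario,
                                n_replicates = n_replicates,
                                n_trees = n_trees, seed = seed, ...)
  params_years <- NULL
  if (!is.null(summary$params)) {
    tp <- summary$params[grepl("^t[1-5]$", summary$params$parameter), ]
    if (nrow(tp) > 0) {
      gt <- prior$generation_time_years
      params_years <- dplyr::mutate(tp, q05 = .data$q05 * gt,
                                    median = .data$median * gt,
                                    q95 = .data$q95 * gt)
    }
  }
  structure(list(summary = summary, observed_stats = observed,
                 params_years = params_years,
                 provenance = list(seed = seed, design = design$name,
                                   n_per_scenario = n_per_scenario,
                                   n_replicates = n_replicates,
                                   n_trees = n_trees,
                                   generation_time_years =
                                     prior$generation_time_years,
                                   registry_version = SUMMARY_REGISTRY_VERSION,
                                   package_version =
                                     as.character(utils::packageVersion("hybridrf")))),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$params_years)) {
    cat("event-time posteriors (years):\n")
    print(x$params_years)
  }
  invisible(x)
}

#' Calibration with pseudo-observed datasets
#'
#' Simulates PODs of known scenario, classifies each against a reference
#' table, and reports the scenario confusion matrix plus (optionally)
#' parameter recovery (bias of the median and coverage of the 90% interval)
#' for PODs of the focal scenario.
#'
#' @param design a [study_design()].
#' @param prior a [prior_spec()].
#' @param pods_per_scenario PODs simulated per scenario.
#' @param scenario_ids scenarios to calibrate over.
#' @param theta fixed POD parameter list (e.g. [mid_prior_theta()]); `NULL`
#'   draws each POD's parameters from the prior.
#' @param n_per_scenario reference-table simulations per scenario.
#' @param n_trees trees per forest.
#' @param recover_params parameters to score for recovery (under each POD's
#'   true scenario); `NULL` skips recovery scoring.
#' @param seed master integer seed.
#' @return a `calibration_result`: list with `confusion` (true x selected
#'   counts), `votes` (per-POD vote tibble), `recovery` (per-POD parameter
#'   estimates with truth) and the reference table used.
#' @export
run_calibration <- function(design, prior = prior_spec(),
                            pods_per_scenario = 10, scenario_ids = 1:6,
                            theta = NULL, n_per_scenario = 500, n_trees = 300,
                            recover_params = NULL, seed = 1) {
  tab <- suppressWarnings(
    build_reference_table(design, prior, n_per_scenario, scenario_ids,
                          seed = derive_seed(seed, 1L)))
  fit <- fit_model_choice(tab, n_trees = n_trees, seed = derive_seed(seed, 2L))
  groups <- names(design$samples)
  rows <- list()
  recov <- list()
  for (sc in scenario_ids) {
    for (i in seq_len(pods_per_scenario)) {
      pod <- make_pod(sc, design, theta = theta, prior = prior,
                      seed = derive_seed(seed, sc * 5000L + i))
      obs <- compute_summaries(pod$dataset, groups = groups)
      res <- classify_scenarios(fit, obs)
      rows[[length(rows) + 1]] <- tibble(
        true_scenario = sc, pod = i, selected = res$selected,
        vote_true = res$votes$vote[res$votes$scenario_id == sc],
        posterior_prob = res$posterior_prob)
      if (!is.null(recover_params)) {
        est <- estimate_parameters(tab, obs, sc, params = recover_params,
                                   n_trees = n_trees,
                                   seed = derive_seed(seed, sc * 7000L + i))
        est$true_scenario <- sc
        est$pod <- i
        est$truth <- vapply(recover_params, function(p) {
          th <- pod$truth$theta
          if (p %in% names(th$times)) th$times[[p]]
          else if (p == "r1") th$r1
          else th$N[[sub("^N_", "", p)]]
        }, numeric(1))
        recov[[length(recov) + 1]] <- est
      }
    }
  }
  votes <- dplyr::bind_rows(rows)
  confusion <- as.data.frame.matrix(
    table(factor(votes$true_scenario, levels = scenario_ids),
          factor(votes$selected, levels = scenario_ids)))
  recovery <- if (length(recov) > 0) dplyr::bind_rows(recov) else NULL
  if (!is.null(recovery))
    recovery$covered <- recovery$truth >= recovery$q05 &
      recovery$truth <= recovery$q95
  structure(list(confusion = confusion, votes = votes, recovery = recovery,
                 table = tab, fit = fit, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> confusion matrix (rows = true, cols = selected):\n")
  print(x$confusion)
  if (!is.null(x$recovery)) {
    cov <- mean(x$recovery$covered)
    cat(sprintf("parameter recovery: 90%% interval coverage %.2f\n", cov))
  }
  invisible(x)
}

#' Chloroplast direction-of-hybridization workflow
#'
#' Finds the fixed diagnostic differences between the two labelled parental
#' haplotype classes, classifies every remaining (hybrid) sequence's
#' maternal lineage, and tabulates directions per locality.
#'
#' @param aln named character vector of aligned sequences (see
#'   [read_haplotype_alignment()]).
#' @param class_a_ids,class_b_ids parental reference sequence ids (the
#'   class-A label conventionally the PAM parent).
#' @param labels class labels reported in calls.
#' @param hybrid_ids sequences to classify; default: all sequences not used
#'   as parental references. May be empty (diagnostics only).
#' @param localities optional tibble `seq_id`, `locality`.
#' @param min_sites minimum scorable events for a confident call.
#' @return list with `diagnostics` (a `diagnostic_set`), `calls` (per-hybrid
#'   tibble) and `directions` (per-locality table).
#' @export
run_cpdna <- function(aln, class_a_ids, class_b_ids, labels = c("PAM", "HIM"),
                      hybrid_ids = NULL, localities = NULL, min_sites = 2) {
  diag <- find_diagnostics(aln, class_a_ids, class_b_ids, labels = labels)
  if (is.null(hybrid_ids))
    hybrid_ids <- setdiff(names(aln), c(class_a_ids, class_b_ids))
  calls <- if (length(hybrid_ids) > 0)
    classify_cohort(aln, diag, ids = hybrid_ids, min_sites = min_sites)
  else tibble(seq_id = character(), call = character(), n_a = integer(),
              n_b = integer(), n_unscorable = integer())
  directions <- summarize_directions(calls, localities)
  list(diagnostics = diag, calls = calls, directions = directions)
}
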
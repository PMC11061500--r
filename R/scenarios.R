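#' Prior specification for the demographic scenarios
#'
#' Uniform priors on event times (in generations), the admixture fraction and
#' per-lineage diploid effective sizes. Times fall into two climate windows:
#' a recent window `[10, 25000]` generations for `t1`/`t2` (events after the
#' regional Last Glacial Maximum) and an older window `[25000, 50000]` for
#' `t3`/`t4` (events during it). The split of the two parental species (`t5`)
#' is drawn from `[100000, t5_upper]`; alternative upper bounds 750000 and
#' 1250000 generations accommodate a potentially earlier parental split.
#'
#' Effective-size priors are a package default, `U[10, 100000]` per lineage,
#' drawn independently; scenario-choice calibration is sensitive to this
#' range, so it is fully configurable.
#'
#' @param t5_upper upper bound for the parental-split time; one of
#'   `200000` (default), `750000`, `1250000`.
#' @param n_range length-2 numeric, uniform range for every lineage's diploid
#'   effective size.
#' @param r1_range length-2 numeric, range of the admixture fraction derived
#'   from the PAM parent.
#' @param generation_time_years years per generation (default 2), used only
#'   when converting event times to calendar years.
#' @return a `prior_spec` object (a named list of ranges).
#' @export
prior_spec <- function(t5_upper = 200000, n_range = c(10, 100000),
                       r1_range = c(0.01, 0.99), generation_time_years = 2) {
  if (!t5_upper %in% c(200000, 750000, 1250000))
    stop_validation("t5_upper must be one of 200000, 750000, 1250000")
  if (length(n_range) != 2 || n_range[1] <= 0 || diff(n_range) <= 0)
    stop_validation("n_range must be an increasing positive pair")
  if (length(r1_range) != 2 || r1_range[1] <= 0 || r1_range[2] >= 1 ||
      diff(r1_range) <= 0)
    stop_validation("r1_range must be an increasing pair inside (0, 1)")
  structure(list(
    t1 = c(10, 25000), t2 = c(10, 25000),
    t3 = c(25000, 50000), t4 = c(25000, 50000),
    t5 = c(100000, t5_upper),
    r1 = r1_range, N = n_range,
    generation_time_years = generation_time_years
  ), class = "prior_spec")
}

# Time symbols used by each scenario and their ordering constraint.
# hyb = hybridization (admixture) time, div = diversification (split) time.
# Scenarios 1-3 are multi-event (two local hybridizations after the PAM
# split); 4-6 are single-event (one hybridization founding a hybrid lineage
# that then diversified).
scenario_time_map <- function(scenario_id) {
  switch(scenario_id,
    `1` = list(hyb = "t1", div = "t2", ordered = c("t1", "t2")),
    `2` = list(hyb = "t3", div = "t4", ordered = c("t3", "t4")),
    `3` = list(hyb = "t2", div = "t4", ordered = NULL),
    `4` = list(div = "t1", hyb = "t2", ordered = c("t1", "t2")),
    `5` = list(div = "t3", hyb = "t4", ordered = c("t3", "t4")),
    `6` = list(div = "t2", hyb = "t4", ordered = NULL)
  )
}

leaf_demes <- function() c("PAM_N", "PAM_S", "HYB_N", "HYB_S", "HIM")

#' Lineages parameterised by a scenario
#'
#' @param scenario_id integer in 1..6.
#' @return character vector of lineage names whose effective sizes the
#'   scenario uses.
#' @export
scenario_lineages <- function(scenario_id) {
  scenario_id <- check_scenario_id(scenario_id)
  base <- c(leaf_demes(), "PAM_anc", "ANC")
  if (scenario_id >= 4) c(base, "HYB_anc") else base
}

check_scenario_id <- function(scenario_id) {
  if (length(scenario_id) != 1 || !scenario_id %in% 1:6)
    stop_validation("scenario_id must be a single integer in 1..6")
  as.character(as.integer(scenario_id))
}

#' Draw scenario parameters from the prior
#'
#' Only the parameters the scenario uses are drawn. Ordering constraints
#' (`t1 < t2`, `t3 < t4` where both appear) are enforced by rejection.
#' Deterministic under a fixed seed.
#'
#' @param prior a [prior_spec()].
#' @param scenario_id integer in 1..6.
#' @param seed optional integer seed.
#' @return a named list with elements `times` (named numeric, generations),
#'   `r1`, `N` (named numeric, one entry per lineage) and
#'   `generation_time_years`.
#' @export
draw_parameters <- function(prior, scenario_id, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  sc <- check_scenario_id(scenario_id)
  tm <- scenario_time_map(sc)
  with_seed(seed, {
    syms <- sort(unique(c(tm$hyb, tm$div, "t5")))
    times <- vapply(syms, function(s) runif(1, prior[[s]][1], prior[[s]][2]),
                    numeric(1))
    if (!is.null(tm$ordered)) {
      for (i in 1:1000) {
        if (times[tm$ordered[1]] < times[tm$ordered[2]]) break
        times[tm$ordered] <- vapply(tm$ordered, function(s)
          runif(1, prior[[s]][1], prior[[s]][2]), numeric(1))
      }
    }
    r1 <- runif(1, prior$r1[1], prior$r1[2])
    lin <- scenario_lineages(as.integer(sc))
    N <- setNames(floor(runif(length(lin), prior$N[1], prior$N[2] + 1)), lin)
    list(times = times, r1 = r1, N = N,
         generation_time_years = prior$generation_time_years)
  })
}

#' Build one of the six demographic scenarios
#'
#' Encodes a scenario as a backward-in-time event list over the five sampled
#' demes (`PAM_N`, `PAM_S`, `HYB_N`, `HYB_S`, `HIM`). Multi-event scenarios
#' (1-3) place one admixture per geographic group (HYB_N from PAM_N x HIM and
#' HYB_S from PAM_S x HIM, sharing a single admixture fraction `r1`) before
#' the PAM north/south lineages merge; single-event scenarios (4-6) first
#' merge the hybrid (and PAM) north/south lineages and then admix the single
#' hybrid ancestor from PAM x HIM. All scenarios end with the parental
#' lineages merging into one ancestral deme at `t5`.
#'
#' @param scenario_id integer in 1..6.
#' @param theta parameter list as returned by [draw_parameters()].
#' @param prior a [prior_spec()] used to validate that `theta` lies in the
#'   prior support.
#' @return a `demographic_scenario` object.
#' @export
build_scenario <- function(scenario_id, theta, prior = prior_spec()) {
  sc <- check_scenario_id(scenario_id)
  tm <- scenario_time_map(sc)
  need <- c(tm$hyb, tm$div, "t5")
  for (s in need) {
    v <- theta$times[[s]]
    if (is.null(v) || is.na(v))
      stop_validation("scenario %s requires parameter %s", sc, s)
    rng <- prior[[s]]
    if (v < rng[1] || v > rng[2])
      stop_validation("%s = %g outside its prior range [%g, %g]",
                      s, v, rng[1], rng[2])
  }
  if (!is.null(tm$ordered) &&
      theta$times[[tm$ordered[1]]] >= theta$times[[tm$ordered[2]]])
    stop_validation("constraint %s < %s violated", tm$ordered[1], tm$ordered[2])
  t_hyb <- theta$times[[tm$hyb]]
  t_div <- theta$times[[tm$div]]
  t5 <- theta$times[["t5"]]
  if (max(t_hyb, t_div) >= t5)
    stop_validation("t5 must postdate (backward in time) every other event")
  if (is.null(theta$r1) || theta$r1 < 0.01 || theta$r1 > 0.99)
    stop_validation("r1 must lie in [0.01, 0.99]")
  lin <- scenario_lineages(as.integer(sc))
  if (!all(lin %in% names(theta$N)) || any(theta$N[lin] <= 0))
    stop_validation("theta$N must give a positive size for each of: %s",
                    paste(lin, collapse = ", "))
  N <- theta$N
  multi <- as.integer(sc) <= 3
  if (multi) {
    if (t_hyb >= t_div)
      stop_validation("hybridization must postdate the PAM split it references")
    ev <- tibble(
      time = c(t_hyb, t_hyb, t_div, t5),
      kind = c("admixture", "admixture", "merge", "merge"),
      child = c("HYB_N", "HYB_S", "PAM_S", "PAM_N"),
      parent_a = c("PAM_N", "PAM_S", "PAM_N", "HIM"),
      parent_b = c("HIM", "HIM", NA, NA),
      frac_a = c(theta$r1, theta$r1, NA, NA),
      new_size = c(NA, NA, N[["PAM_anc"]], N[["ANC"]]))
  } else {
    if (t_div >= t_hyb)
      stop_validation("hybrid diversification must postdate the founding hybridization")
    ev <- tibble(
      time = c(t_div, t_div, t_hyb, t5),
      kind = c("merge", "merge", "admixture", "merge"),
      child = c("HYB_S", "PAM_S", "HYB_N", "PAM_N"),
      parent_a = c("HYB_N", "PAM_N", "PAM_N", "HIM"),
      parent_b = c(NA, NA, "HIM", NA),
      frac_a = c(NA, NA, theta$r1, NA),
      new_size = c(N[["HYB_anc"]], N[["PAM_anc"]], NA, N[["ANC"]]))
  }
  demographic_scenario(events = ev, sizes = N[leaf_demes()],
                       scenario_id = as.integer(sc), theta = theta)
}

#' Construct a demographic scenario from an explicit event list
#'
#' Lower-level constructor for arbitrary split/admixture histories (used for
#' custom models such as a plain two-deme split). Events act backward in
#' time; a `merge` moves all lineages of `child` into `parent_a`, whose
#' diploid size becomes `new_size` (the ancestral lineage's size); an
#' `admixture` routes each lineage of `child` to `parent_a` with probability
#' `frac_a`, else to `parent_b`. Ties at identical times are resolved in row
#' order.
#'
#' @param events tibble with columns `time`, `kind` (`"merge"`/`"admixture"`),
#'   `child`, `parent_a`, `parent_b`, `frac_a`, `new_size`.
#' @param sizes named numeric, diploid effective size per sampled deme.
#' @param scenario_id optional integer label.
#' @param theta optional parameter list stored for provenance.
#' @return a `demographic_scenario`.
#' @export
demographic_scenario <- function(events, sizes, scenario_id = NA_integer_,
                                 theta = NULL) {
  events <- as_tibble(events)
  need <- c("time", "kind", "child", "parent_a", "parent_b", "frac_a", "new_size")
  if (!all(need %in% names(events)))
    stop_validation("events must have columns: %s", paste(need, collapse = ", "))
  if (any(events$time <= 0)) stop_validation("event times must be positive")
  ord <- order(events$time)
  events <- events[ord, ]
  if (is.null(names(sizes)) || any(sizes <= 0))
    stop_validation("sizes must be a named positive vector (one per sampled deme)")
  adm <- events$kind == "admixture"
  if (any(adm & (is.na(events$frac_a) | events$frac_a <= 0 | events$frac_a >= 1)))
    stop_validation("admixture frac_a must lie in (0, 1)")
  if (any(!adm & (is.na(events$new_size) | events$new_size <= 0)))
    stop_validation("merge events need a positive new_size for the host deme")
  # occupancy check: every event must reference live demes and the history
  # must end with a single ancestral deme
  alive <- names(sizes)
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    refs <- c(e$child, e$parent_a, if (e$kind == "admixture") e$parent_b)
    if (!all(refs %in% alive))
      stop_validation("event at time %g references a deme not alive then (%s)",
                      e$time, paste(setdiff(refs, alive), collapse = ", "))
    alive <- setdiff(alive, e$child)
  }
  if (length(alive) != 1)
    stop_validation("events leave %d demes unmerged; expected a single ancestor",
                    length(alive))
  structure(list(scenario_id = scenario_id, leaf_demes = names(sizes),
                 sizes = sizes, events = events, theta = theta),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("<demographic_scenario> id=%s, %d sampled demes, %d events\n",
              x$scenario_id, length(x$leaf_demes), nrow(x$events)))
  print(x$events)
  invisible(x)
}

#' Classify a scenario by number of hybridization events
#'
#' Structural predicate: scenarios with two admixture events model repeated
#' local hybridization (`"multi-event"`); a single admixture founds one
#' hybrid lineage (`"single-event"`); no admixture means no hybrid origin.
#'
#' @param scenario a `demographic_scenario`.
#' @return one of `"multi-event"`, `"single-event"`, `"no-hybridization"`.
#' @export
scenario_origin_class <- function(scenario) {
  stopifnot(inherits(scenario, "demographic_scenario"))
  k <- sum(scenario$events$kind == "admixture")
  if (k >= 2) "multi-event" else if (k == 1) "single-event" else "no-hybridization"
}

#' Convert event times from generations to calendar years
#'
#' @param theta parameter list with `times` in generations and
#'   `generation_time_years` (default 2 years per generation).
#' @param generation_time_years override for the generation time.
#' @return named numeric vector of event times in years.
#' @export
generations_to_years <- function(theta,
                                 generation_time_years = NULL) {
  gt <- generation_time_years %||%
    theta$generation_time_years %||% 2
  times <- if (is.list(theta)) theta$times else theta
  times * gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / read a prior specification
#'
#' Round-trip safe YAML serialization of prior ranges, size priors and the
#' generation time.
#'
#' @param prior a [prior_spec()].
#' @param path file path.
#' @return `write_prior_config()` returns `path` invisibly;
#'   `read_prior_config()` returns a [prior_spec()].
#' @export
write_prior_config <- function(prior, path) {
  stopifnot(inherits(prior, "prior_spec"))
  yaml::write_yaml(list(t5_upper = prior$t5[2], n_range = prior$N,
                        r1_range = prior$r1,
                        generation_time_years = prior$generation_time_years),
                   path)
  invisible(path)
}

#' @rdname write_prior_config
#' @export
read_prior_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  prior_spec(t5_upper = cfg$t5_upper, n_range = as.numeric(cfg$n_range),
             r1_range = as.numeric(cfg$r1_range),
             generation_time_years = cfg$generation_time_years)
}
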
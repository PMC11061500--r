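#' Sampling configuration for the coalescent simulator
#'
#' Number of diploid individuals sampled at present per deme. Every sampled
#' deme must be a leaf deme of the scenario; demes may have zero samples.
#'
#' @param ... named integer counts, e.g. `PAM_N = 41, HIM = 1`, or a single
#'   named vector.
#' @return a named integer vector of class `sample_config`.
#' @export
sample_config <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_validation("sample_config entries must be named by deme")
  if (any(x < 0) || sum(x) < 1)
    stop_validation("sample counts must be >= 0 and total >= 1 individual")
  structure(setNames(as.integer(x), names(x)), class = "sample_config")
}

# Translate a scenario + config into the flat 0-based arrays the C++ core
# consumes. Slot order is the scenario's leaf-deme order.
scenario_to_cpp <- function(scenario, config) {
  stopifnot(inherits(scenario, "demographic_scenario"))
  demes <- scenario$leaf_demes
  extra <- setdiff(names(config), demes)
  if (length(extra) > 0)
    stop_validation("sampled deme(s) not in the scenario: %s",
                    paste(extra, collapse = ", "))
  n_ind <- setNames(integer(length(demes)), demes)
  n_ind[names(config)] <- config
  if (sum(n_ind) * 2 < 2) stop_validation("need at least 2 gene copies")
  ev <- scenario$events
  slot <- function(x) match(x, demes) - 1L
  list(ev_time = as.numeric(ev$time),
       ev_type = ifelse(ev$kind == "admixture", 1L, 0L),
       ev_child = slot(ev$child),
       ev_pa = slot(ev$parent_a),
       ev_pb = ifelse(is.na(ev$parent_b), -1L, slot(ev$parent_b)),
       ev_frac = ifelse(is.na(ev$frac_a), 0, ev$frac_a),
       ev_size = ifelse(is.na(ev$new_size), 1, ev$new_size),
       leaf_sizes = as.numeric(scenario$sizes[demes]),
       n_ind = unname(n_ind),
       demes = demes)
}

#' Simulate a single gene tree under a demographic scenario
#'
#' Runs the structured coalescent backward in time: within each deme the
#' waiting time to the next coalescence among `k` gene copies of a diploid
#' deme of size `N` is exponential with rate `k(k-1)/2 / (2N)` per
#' generation; merge events move all lineages of the child deme to its
#' parent, admixture events route each lineage independently to one of two
#' parents.
#'
#' @param scenario a `demographic_scenario`.
#' @param config a [sample_config()].
#' @param seed optional integer seed.
#' @return a `gene_tree`: list with `n_tips`, 1-based `parent` (0 at the
#'   root), `child1`/`child2`, `node_time` (generations; tips at 0),
#'   `tip_deme`, `tip_individual` and `tip_copy`. Tips are ordered deme by
#'   deme, two consecutive copies per individual.
#' @export
simulate_tree <- function(scenario, config, seed = NULL) {
  cc <- scenario_to_cpp(scenario, config)
  raw <- with_seed(seed, cpp_sim_tree(cc$ev_time, cc$ev_type, cc$ev_child,
                                      cc$ev_pa, cc$ev_pb, cc$ev_frac,
                                      cc$ev_size, cc$leaf_sizes, cc$n_ind))
  tip_deme <- rep(cc$demes, times = 2 * cc$n_ind)
  ind <- unlist(lapply(seq_along(cc$demes), function(d) {
    if (cc$n_ind[d] == 0) return(character(0))
    rep(sprintf("%s_%02d", cc$demes[d], seq_len(cc$n_ind[d])), each = 2)
  }))
  structure(list(n_tips = raw$n_tips,
                 parent = raw$parent + 1L,        # 0 marks the root
                 child1 = raw$child1 + 1L,
                 child2 = raw$child2 + 1L,
                 node_time = raw$node_time,
                 tip_deme = tip_deme,
                 tip_individual = ind,
                 tip_copy = rep(0:1, length.out = raw$n_tips)),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d tips, TMRCA %.1f generations\n",
              x$n_tips, tmrca(x)))
  invisible(x)
}

#' Time to the most recent common ancestor of a gene tree
#' @param tree a `gene_tree`.
#' @return TMRCA in generations.
#' @export
tmrca <- function(tree) tree$node_time[2 * tree$n_tips - 1]

#' Simulate TMRCA replicates
#'
#' Fast path that simulates `reps` independent gene trees and returns only
#' their root times (for Monte Carlo checks against coalescent expectations).
#'
#' @inheritParams simulate_tree
#' @param reps number of independent trees.
#' @return numeric vector of TMRCAs in generations.
#' @export
simulate_tmrca <- function(scenario, config, reps, seed = NULL) {
  cc <- scenario_to_cpp(scenario, config)
  with_seed(seed, cpp_sim_tmrca(cc$ev_time, cc$ev_type, cc$ev_child,
                                cc$ev_pa, cc$ev_pb, cc$ev_frac, cc$ev_size,
                                cc$leaf_sizes, cc$n_ind, as.integer(reps)))
}

#' Place a single mutation on a gene tree
#'
#' One branch is chosen with probability proportional to its length; all tip
#' copies descending from it carry the derived allele. Because every
#' non-root branch subtends a proper, non-empty subset of the tips, the
#' resulting locus is always polymorphic in the sample.
#'
#' @param tree a `gene_tree` from [simulate_tree()].
#' @param seed optional integer seed.
#' @return logical vector over tips, `TRUE` for derived-allele carriers.
#' @export
drop_single_mutation <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  m <- 2 * tree$n_tips - 1
  len <- ifelse(tree$parent > 0,
                tree$node_time[pmax(tree$parent, 1)] - tree$node_time, 0)
  sel <- with_seed(seed, sample.int(m, 1, prob = len))
  carrier <- logical(tree$n_tips)
  stack <- sel
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= tree$n_tips) carrier[v] <- TRUE
    else stack <- c(stack, tree$child1[v], tree$child2[v])
  }
  carrier
}

#' Newick serialization of a gene tree
#'
#' Debug export of the per-locus true genealogy; tip labels are
#' `individual.copy`.
#'
#' @param tree a `gene_tree`.
#' @return a newick string (branch lengths in generations).
#' @export
gene_tree_newick <- function(tree) {
  lab <- paste0(tree$tip_individual, ".", tree$tip_copy)
  build <- function(v) {
    bl <- if (tree$parent[v] > 0)
      tree$node_time[tree$parent[v]] - tree$node_time[v] else 0
    if (v <= tree$n_tips) return(sprintf("%s:%.12g", lab[v], bl))
    sprintf("(%s,%s):%.12g", build(tree$child1[v]), build(tree$child2[v]), bl)
  }
  paste0(sub(":[^:]*$", "", build(2 * tree$n_tips - 1)), ";")
}

#' Simulate an unlinked-SNP dataset under a demographic scenario
#'
#' Each locus is an independent gene tree with a single mutation placed
#' proportionally to branch length. Trees are sampled with probability
#' proportional to their total branch length (the low-mutation-rate
#' infinite-sites limit, under which a variable site is proportionally more
#' likely on a longer genealogy), so the unconditioned site-frequency
#' spectrum follows the neutral expectation; the length weighting uses
#' capped-weight rejection with a pilot-calibrated cap. Loci are then
#' accepted only if the pooled-sample minor-allele frequency reaches
#' `min_maf` (rejection with an attempt cap per locus, mirroring the
#' ascertainment of a MAF-filtered SNP panel). Diploid dosages pair the two
#' gene copies of each individual; the output has no missing data.
#'
#' @inheritParams simulate_tree
#' @param n_loci number of SNP loci.
#' @param min_maf pooled minor-allele frequency threshold in `[0, 0.5)`.
#' @param max_attempts per-locus rejection cap; exceeding it raises a
#'   runtime error naming the scenario (it signals a parameter draw under
#'   which polymorphic loci at this MAF are vanishingly rare).
#' @return a [snp_dataset()] with individuals grouped by deme.
#' @export
simulate_snp_dataset <- function(scenario, config, n_loci, min_maf = 0.05,
                                 seed = NULL, max_attempts = 10000) {
  if (n_loci < 1) stop_validation("n_loci must be >= 1")
  if (min_maf < 0 || min_maf >= 0.5)
    stop_validation("min_maf must be in [0, 0.5)")
  cc <- scenario_to_cpp(scenario, config)
  dos <- tryCatch(
    with_seed(seed, cpp_sim_dosage(cc$ev_time, cc$ev_type, cc$ev_child,
                                   cc$ev_pa, cc$ev_pb, cc$ev_frac, cc$ev_size,
                                   cc$leaf_sizes, cc$n_ind,
                                   as.integer(n_loci), min_maf,
                                   as.integer(max_attempts))),
    error = function(e) {
      stop_runtime("scenario %s: %s", scenario$scenario_id, conditionMessage(e))
    })
  demes <- rep(cc$demes, times = cc$n_ind)
  ids <- unlist(lapply(seq_along(cc$demes), function(d) {
    if (cc$n_ind[d] == 0) return(character(0))
    sprintf("%s_%02d", cc$demes[d], seq_len(cc$n_ind[d]))
  }))
  loci <- tibble(locus_id = sprintf("L%05d", seq_len(n_loci)),
                 clone_id = sprintf("C%05d", seq_len(n_loci)),
                 reproducibility = 1,
                 allele_ref = "A", allele_alt = "T")
  ds <- snp_dataset(unname(dos), loci,
                    tibble(individual_id = ids, group = demes))
  attr(ds, "attempts") <- attr(dos, "attempts")
  ds
}
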
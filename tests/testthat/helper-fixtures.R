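# Shared fixture builders. Everything is generated in code at test time.

# A single panmictic deme of diploid size N (no events).
panmictic_scenario <- function(N = 1000, deme = "POP") {
  demographic_scenario(
    tibble::tibble(time = numeric(), kind = character(), child = character(),
                   parent_a = character(), parent_b = character(),
                   frac_a = numeric(), new_size = numeric()),
    sizes = stats::setNames(N, deme))
}

# Two demes A and B of size N that merged t generations ago.
two_deme_split <- function(t, N = 1000, N_anc = N) {
  demographic_scenario(
    tibble::tibble(time = t, kind = "merge", child = "B", parent_a = "A",
                   parent_b = NA, frac_a = NA, new_size = N_anc),
    sizes = c(A = N, B = N))
}

# Small genotype dataset built by hand; dosage matrix is individuals x loci.
toy_dataset <- function(dosages, groups = NULL, repro = NULL,
                        clone = NULL) {
  n_ind <- nrow(dosages)
  n_loc <- ncol(dosages)
  loci <- tibble::tibble(
    locus_id = sprintf("L%03d", seq_len(n_loc)),
    clone_id = clone %||% sprintf("C%03d", seq_len(n_loc)),
    reproducibility = repro %||% rep(1, n_loc),
    allele_ref = "A", allele_alt = "T")
  ind <- tibble::tibble(individual_id = sprintf("i%02d", seq_len(n_ind)),
                        group = groups %||% rep("G1", n_ind))
  snp_dataset(dosages, loci, ind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-rolled reference table with planted, well-separated scenario classes
# (used to test the RF machinery independently of the simulator).
separable_table <- function(n_per_class = 150, k = 2, shift = 5, seed = 1,
                            sd = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(k), function(cl) {
    cbind(scenario_id = cl,
          t1 = runif(n_per_class, 10, 25000), r1 = runif(n_per_class, .01, .99),
          x1 = rnorm(n_per_class, shift * (cl - 1), sd),
          x2 = rnorm(n_per_class, -shift * (cl - 1), sd),
          x3 = rnorm(n_per_class, 0, sd))
  }))
  tab <- tibble::as_tibble(as.data.frame(rows))
  attr(tab, "stat_names") <- c("x1", "x2", "x3")
  attr(tab, "param_names") <- c("t1", "r1")
  attr(tab, "provenance") <- list(registry_version = "toy")
  class(tab) <- c("reference_table", class(tab))
  tab
}
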
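#' SNP filtering cascade
#'
#' The locus/individual filters applied to DArT-style panels before
#' demographic inference, in their conventional order: locus reproducibility
#' and call rate, individual call rate, monomorphic removal, secondary-SNP
#' thinning (one random SNP per sequenced fragment so loci are effectively
#' unlinked), group-polymorphism filtering, and a pooled minor-allele
#' frequency threshold. Call rates are always recomputed on the current
#' (already filtered) matrix, so the order of steps matters.
#'
#' All filters are idempotent and return a new dataset; empty results are
#' permitted (with a warning).
#'
#' @param ds a [snp_dataset()].
#' @param min_reproducibility,min_locus_call_rate,min_individual_call_rate
#'   thresholds in `[0, 1]`; loci/individuals at or above the threshold are
#'   kept.
#' @name filters
NULL

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_validation("%s must be a single value in [0, 1]", what)
}

warn_if_empty <- function(ds, axis) {
  n <- if (axis == "loci") ncol(ds$dosages) else nrow(ds$dosages)
  if (n == 0) warn(sprintf("filter removed all %s", axis))
  ds
}

#' @rdname filters
#' @return a filtered [snp_dataset()]; individual and locus order unchanged.
#' @export
filter_loci <- function(ds, min_reproducibility = 1, min_locus_call_rate = 1) {
  check_fraction(min_reproducibility, "min_reproducibility")
  check_fraction(min_locus_call_rate, "min_locus_call_rate")
  call_rate <- colMeans(!is.na(ds$dosages))
  keep <- ds$loci$reproducibility >= min_reproducibility &
    call_rate >= min_locus_call_rate
  keep[is.na(keep)] <- FALSE
  warn_if_empty(subset_snp_dataset(ds, loc_keep = which(keep)), "loci")
}

#' @rdname filters
#' @export
filter_individuals <- function(ds, min_individual_call_rate = 1) {
  check_fraction(min_individual_call_rate, "min_individual_call_rate")
  call_rate <- rowMeans(!is.na(ds$dosages))
  warn_if_empty(
    subset_snp_dataset(ds, ind_keep = which(call_rate >= min_individual_call_rate)),
    "individuals")
}

#' @rdname filters
#' @export
remove_monomorphic <- function(ds) {
  freq <- pooled_alt_freq(ds$dosages)
  keep <- !is.na(freq) & freq > 0 & freq < 1
  warn_if_empty(subset_snp_dataset(ds, loc_keep = which(keep)), "loci")
}

# Alt-allele frequency over all non-missing diploid calls, per locus.
pooled_alt_freq <- function(dos) {
  n_copies <- 2 * colSums(!is.na(dos))
  alt <- colSums(dos, na.rm = TRUE)
  ifelse(n_copies > 0, alt / n_copies, NA_real_)
}

#' Thin secondary SNPs to one per sequenced fragment
#'
#' Keeps exactly one locus per `clone_id`, chosen uniformly at random, so the
#' retained loci are effectively unlinked. Deterministic for a fixed seed.
#'
#' @param ds a [snp_dataset()].
#' @param seed integer seed for the random choice; `NULL` uses the current
#'   RNG stream.
#' @return a filtered [snp_dataset()] with one locus per clone.
#' @export
thin_secondary_snps <- function(ds, seed = NULL) {
  if (ncol(ds$dosages) == 0) return(ds)
  keep <- with_seed(seed, {
    idx <- seq_len(nrow(ds$loci))
    picked <- vapply(split(idx, ds$loci$clone_id), function(g) {
      if (length(g) == 1) g else g[sample.int(length(g), 1)]
    }, integer(1))
    sort(unname(picked))
  })
  subset_snp_dataset(ds, loc_keep = keep)
}

#' Filter loci on within-group polymorphism
#'
#' Retains the most informative loci for admixture inference by removing
#' loci that are monomorphic in the listed groups. Two readings are
#' supported: `mode = "strict"` (default) keeps a locus only when it is
#' polymorphic within *every* listed group; `mode = "weak"` drops a locus
#' only when it is monomorphic in *all* listed groups simultaneously.
#'
#' @param ds a [snp_dataset()].
#' @param groups named list of group-label vectors, e.g.
#'   `list(PAM = c("PAM_N", "PAM_S"), HYB = c("HYB_N", "HYB_S"))`; each entry
#'   is pooled into one group for the polymorphism test.
#' @param mode `"strict"` or `"weak"` (see Details).
#' @return a filtered [snp_dataset()].
#' @export
filter_group_polymorphism <- function(ds, groups, mode = c("strict", "weak")) {
  mode <- match.arg(mode)
  if (!is.list(groups) || length(groups) == 0)
    stop_validation("`groups` must be a non-empty list of group-label vectors")
  poly <- vapply(groups, function(g) {
    idx <- group_index(ds, g)
    f <- pooled_alt_freq(ds$dosages[idx, , drop = FALSE])
    !is.na(f) & f > 0 & f < 1
  }, logical(ncol(ds$dosages)))
  poly <- matrix(poly, ncol = length(groups))
  keep <- if (mode == "strict") rowSums(poly) == length(groups)
          else rowSums(poly) > 0
  warn_if_empty(subset_snp_dataset(ds, loc_keep = which(keep)), "loci")
}

#' Filter loci on pooled minor-allele frequency
#'
#' MAF is computed over the non-missing dosages of all individuals; the
#' boundary is inclusive (a locus at exactly `min_maf` is kept).
#'
#' @param ds a [snp_dataset()].
#' @param min_maf threshold in `[0, 0.5]`.
#' @return a filtered [snp_dataset()].
#' @export
filter_maf <- function(ds, min_maf = 0.05) {
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf > 0.5)
    stop_validation("min_maf must be in [0, 0.5]")
  freq <- pooled_alt_freq(ds$dosages)
  maf <- pmin(freq, 1 - freq)
  keep <- !is.na(maf) & maf >= min_maf
  warn_if_empty(subset_snp_dataset(ds, loc_keep = which(keep)), "loci")
}
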
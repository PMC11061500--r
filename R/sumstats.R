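#' Per-locus alternative-allele frequency within a group
#'
#' Frequency = alt copies / non-missing copies. Loci with no non-missing
#' calls in the group get `NA` (and are excluded from that group's
#' statistics downstream).
#'
#' @param ds a [snp_dataset()].
#' @param group one or more group labels (pooled).
#' @return tibble with columns `locus_id`, `freq`, `n_copies`.
#' @export
allele_freq <- function(ds, group) {
  f <- freq_of(ds$dosages, group_index(ds, group))
  tibble(locus_id = ds$loci$locus_id, freq = f$freq, n_copies = f$n_copies)
}

# freq/copy counts for a row subset of a dosage matrix (plain list; the hot
# path used by compute_summaries and the reference-table builder)
freq_of <- function(dos, idx) {
  sub <- dos[idx, , drop = FALSE]
  n_copies <- 2 * colSums(!is.na(sub))
  freq <- ifelse(n_copies > 0, colSums(sub, na.rm = TRUE) / n_copies, NA_real_)
  list(freq = unname(freq), n_copies = unname(n_copies))
}

# Unbiased expected heterozygosity per locus: 2p(1-p) * n/(n-1), n = gene
# copies. Defined for n >= 2, i.e. even a single diploid individual.
he_unbiased <- function(p, n_copies) {
  ifelse(n_copies >= 2, 2 * p * (1 - p) * n_copies / (n_copies - 1), NA_real_)
}

fst_from_freq <- function(a, b, clip = FALSE) {
  hw <- (he_unbiased(a$freq, a$n_copies) + he_unbiased(b$freq, b$n_copies)) / 2
  hb <- a$freq * (1 - b$freq) + b$freq * (1 - a$freq)
  ok <- !is.na(hw) & !is.na(hb)
  if (!any(ok) || mean(hb[ok]) == 0) return(NA_real_)
  fst <- 1 - mean(hw[ok]) / mean(hb[ok])
  if (clip) fst <- min(max(fst, -0.1), 1)
  fst
}

nei_from_freq <- function(a, b, cap = 10) {
  ok <- !is.na(a$freq) & !is.na(b$freq)
  pa <- a$freq[ok]; pb <- b$freq[ok]
  jxy <- sum(pa * pb + (1 - pa) * (1 - pb))
  jx <- sum(pa^2 + (1 - pa)^2)
  jy <- sum(pb^2 + (1 - pb)^2)
  ident <- jxy / sqrt(jx * jy)
  if (!is.finite(ident) || ident <= 0) return(structure(cap, capped = TRUE))
  min(-log(ident), cap)
}

f3_from_freq <- function(t_, a, b) {
  ok <- !is.na(t_$freq) & !is.na(a$freq) & !is.na(b$freq) & t_$n_copies >= 2
  corr <- t_$freq * (1 - t_$freq) / (t_$n_copies - 1)
  mean(((t_$freq - a$freq) * (t_$freq - b$freq) - corr)[ok])
}

f4_from_freq <- function(a, b, c_, d) {
  ok <- !is.na(a$freq) & !is.na(b$freq) & !is.na(c_$freq) & !is.na(d$freq)
  mean(((a$freq - b$freq) * (c_$freq - d$freq))[ok])
}

#' Expected heterozygosity of a group
#'
#' Per-locus unbiased estimator `2p(1-p) n/(n-1)` (n = non-missing gene
#' copies), summarised as mean and variance across loci.
#'
#' @inheritParams allele_freq
#' @return tibble with one row: `mean_he`, `var_he`, `n_loci` used.
#' @export
expected_heterozygosity <- function(ds, group) {
  f <- freq_of(ds$dosages, group_index(ds, group))
  he <- he_unbiased(f$freq, f$n_copies)
  he <- he[!is.na(he)]
  tibble(mean_he = mean(he),
         var_he = if (length(he) > 1) var(he) else 0,
         n_loci = length(he))
}

#' Hudson's FST between two groups (ratio of averages)
#'
#' `FST = 1 - mean_loci(Hw) / mean_loci(Hb)` with `Hw` the average of the two
#' within-group unbiased heterozygosities and
#' `Hb = pA(1-pB) + pB(1-pA)`. Loci missing entirely in either group are
#' dropped pairwise. The raw (unclipped) value is returned; for display it
#' is conventionally clipped to `[-0.1, 1]`.
#'
#' @param ds a [snp_dataset()].
#' @param group_a,group_b group labels (each may pool several).
#' @param clip clip the returned value to `[-0.1, 1]` (default `FALSE`).
#' @return a single numeric FST estimate.
#' @export
hudson_fst <- function(ds, group_a, group_b, clip = FALSE) {
  fst_from_freq(freq_of(ds$dosages, group_index(ds, group_a)),
                freq_of(ds$dosages, group_index(ds, group_b)), clip = clip)
}

#' Nei's standard genetic distance between two groups
#'
#' `D = -ln( sum_l sum_alleles pA pB / sqrt(sum pA^2 * sum pB^2) )` over the
#' two alleles of each biallelic locus, sums taken across loci. Identity 0
#' (fixed opposite alleles at every locus) would give `+Inf`; the value is
#' capped at `cap` with an attribute flag.
#'
#' @inheritParams hudson_fst
#' @param cap value substituted for infinite distances.
#' @return a single numeric distance (attribute `capped` when the guard
#'   applied).
#' @export
nei_distance <- function(ds, group_a, group_b, cap = 10) {
  nei_from_freq(freq_of(ds$dosages, group_index(ds, group_a)),
                freq_of(ds$dosages, group_index(ds, group_b)), cap = cap)
}

#' f3 admixture statistic
#'
#' `f3(T; A, B) = mean_loci[ (pT-pA)(pT-pB) - pT(1-pT)/(nT-1) ]` with `nT`
#' the target's non-missing gene copies (the standard small-sample
#' correction for the target). Significantly negative values indicate that
#' the target is admixed between proxies of the two sources.
#'
#' @param ds a [snp_dataset()].
#' @param target,source_a,source_b group labels.
#' @return a single numeric f3 value.
#' @export
f3_stat <- function(ds, target, source_a, source_b) {
  f3_from_freq(freq_of(ds$dosages, group_index(ds, target)),
               freq_of(ds$dosages, group_index(ds, source_a)),
               freq_of(ds$dosages, group_index(ds, source_b)))
}

#' f4 statistic
#'
#' `f4(A, B; C, D) = mean_loci (pA-pB)(pC-pD)`; values far from zero
#' indicate correlated drift (gene flow) connecting the two pairs.
#'
#' @param ds a [snp_dataset()].
#' @param a,b,c,d group labels.
#' @return a single numeric f4 value.
#' @export
f4_stat <- function(ds, a, b, c, d) {
  f4_from_freq(freq_of(ds$dosages, group_index(ds, a)),
               freq_of(ds$dosages, group_index(ds, b)),
               freq_of(ds$dosages, group_index(ds, c)),
               freq_of(ds$dosages, group_index(ds, d)))
}

# Version tag for the statistic registry; recorded in reference tables and
# checked between observed and simulated summary vectors.
SUMMARY_REGISTRY_VERSION <- "hybridrf-ss-1"

# Hot path: summary vector from a dosage matrix and a named list of group
# row-indices (order defines the vector order). `compute_summaries` is the
# documented wrapper.
summaries_core <- function(dos, gidx) {
  groups <- names(gidx)
  freqs <- lapply(gidx, function(i) freq_of(dos, i))
  stats <- numeric(0)
  for (g in groups) {
    f <- freqs[[g]]
    defined <- !is.na(f$freq)
    he <- he_unbiased(f$freq, f$n_copies)
    he <- he[!is.na(he)]
    stats[paste0("prop_poly_", g)] <-
      mean(f$freq[defined] > 0 & f$freq[defined] < 1)
    stats[paste0("mean_he_", g)] <- mean(he)
    stats[paste0("var_he_", g)] <- if (length(he) > 1) var(he) else 0
  }
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        tag <- paste(groups[c(i, j)], collapse = ".")
        stats[paste0("fst_", tag)] <- fst_from_freq(freqs[[i]], freqs[[j]])
        stats[paste0("nei_", tag)] <-
          as.numeric(nei_from_freq(freqs[[i]], freqs[[j]]))
      }
    }
  }
  canonical <- c("PAM_N", "PAM_S", "HYB_N", "HYB_S", "HIM")
  if (all(canonical %in% groups)) {
    hyb_pool <- freq_of(dos, c(gidx[["HYB_N"]], gidx[["HYB_S"]]))
    stats["f3_HYB_N"] <- f3_from_freq(freqs[["HYB_N"]], freqs[["PAM_N"]],
                                      freqs[["HIM"]])
    stats["f3_HYB_S"] <- f3_from_freq(freqs[["HYB_S"]], freqs[["PAM_S"]],
                                      freqs[["HIM"]])
    stats["f4_PAM.HYB_HIM"] <- f4_from_freq(freqs[["PAM_N"]], freqs[["PAM_S"]],
                                            hyb_pool, freqs[["HIM"]])
  }
  stats
}

#' Compute the fixed-order summary-statistic vector
#'
#' The same vector is computed for the observed dataset and for every
#' simulated dataset in a reference table: per group the proportion of
#' polymorphic loci and the mean and variance across loci of expected
#' heterozygosity; per group pair mean Hudson FST and Nei's standard
#' distance; and, when the five canonical demes (`PAM_N`, `PAM_S`, `HYB_N`,
#' `HYB_S`, `HIM`) are all present, the admixture statistics
#' `f3(HYB_g; PAM_g, HIM)` for each geographic group and
#' `f4(PAM_N, PAM_S; HYB_pooled, HIM)`.
#'
#' The function is pure (no input mutation, bit-identical reruns) and the
#' order of the vector is fixed given the group list; the registry version
#' is attached as an attribute and stored in reference tables.
#'
#' @param ds a [snp_dataset()] with group labels set.
#' @param groups character vector of group labels defining the vector order;
#'   defaults to the groups present, in order of first appearance.
#' @return named numeric vector (attribute `registry_version`).
#' @export
compute_summaries <- function(ds, groups = NULL) {
  if (is.null(groups)) groups <- unique(ds$individuals$group)
  if (any(is.na(groups)) || length(groups) < 1)
    stop_validation("dataset needs non-missing group labels")
  gidx <- lapply(setNames(groups, groups), function(g) group_index(ds, g))
  stats <- summaries_core(ds$dosages, gidx)
  attr(stats, "registry_version") <- SUMMARY_REGISTRY_VERSION
  stats
}

#' Header of the summary vector for a group list
#'
#' @param groups character vector of group labels.
#' @return character vector naming every statistic, in order.
#' @export
summary_header <- function(groups) {
  nm <- as.vector(vapply(groups, function(g)
    paste0(c("prop_poly_", "mean_he_", "var_he_"), g), character(3)))
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    nm <- c(nm, unlist(lapply(pairs, function(p) {
      tag <- paste(p, collapse = ".")
      c(paste0("fst_", tag), paste0("nei_", tag))
    })))
  }
  canonical <- c("PAM_N", "PAM_S", "HYB_N", "HYB_S", "HIM")
  if (all(canonical %in% groups))
    nm <- c(nm, "f3_HYB_N", "f3_HYB_S", "f4_PAM.HYB_HIM")
  nm
}
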
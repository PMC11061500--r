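#' Study designs emulated by the synthetic-data generator
#'
#' Two sampling designs are modelled. The *cluster* design genotypes 118
#' diploid individuals (81 PAM split 41 north / 40 south, 36 hybrids split
#' 18/18, and a single HIM herbarium specimen) at 338 unlinked biallelic
#' SNPs. The *population* design restricts to one northern and one southern
#' region: 27 individuals (14 north = 7 PAM + 7 HYB, 12 south = 6 PAM +
#' 6 HYB, 1 HIM) at 181 SNPs. Only the totals are fixed by the study; the
#' per-deme split of the population design is a package default recorded in
#' fixture provenance. Both designs use a pooled MAF threshold of 0.05.
#'
#' @param name `"cluster"` or `"population"`.
#' @param samples optional [sample_config()] override; its total must match
#'   the design's individual count.
#' @param n_loci optional override of the SNP count.
#' @param min_maf pooled MAF threshold.
#' @return a `study_design`: list with `name`, `samples`, `n_loci`,
#'   `min_maf`.
#' @export
study_design <- function(name = c("cluster", "population"), samples = NULL,
                         n_loci = NULL, min_maf = 0.05) {
  name <- match.arg(name)
  defaults <- switch(name,
    cluster = list(samples = sample_config(PAM_N = 41, PAM_S = 40,
                                           HYB_N = 18, HYB_S = 18, HIM = 1),
                   n_loci = 338, total = 118),
    population = list(samples = sample_config(PAM_N = 7, PAM_S = 6,
                                              HYB_N = 7, HYB_S = 6, HIM = 1),
                      n_loci = 181, total = 27))
  if (!is.null(samples)) {
    if (sum(samples) != defaults$total)
      stop_validation("custom sample sizes total %d; the %s design has %d individuals",
                      sum(samples), name, defaults$total)
    defaults$samples <- samples
  }
  if (!is.null(n_loci)) defaults$n_loci <- as.integer(n_loci)
  structure(list(name = name, samples = defaults$samples,
                 n_loci = defaults$n_loci, min_maf = min_maf),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %s: %d individuals (%s), %d loci, MAF >= %.2f\n",
              x$name, sum(x$samples),
              paste(sprintf("%s=%d", names(x$samples), x$samples), collapse = ", "),
              x$n_loci, x$min_maf))
  invisible(x)
}

#' Mid-prior parameter vector for a scenario
#'
#' A representative parameter point: ordered time pairs at the 25% and 75%
#' quantiles of their shared prior range (so the ordering constraint holds
#' with margin), unconstrained times and sizes at the range midpoint, and
#' `r1 = 0.5`.
#'
#' @param scenario_id integer in 1..6.
#' @param prior a [prior_spec()].
#' @return parameter list in the format of [draw_parameters()].
#' @export
mid_prior_theta <- function(scenario_id, prior = prior_spec()) {
  sc <- check_scenario_id(scenario_id)
  tm <- scenario_time_map(sc)
  syms <- sort(unique(c(tm$hyb, tm$div, "t5")))
  times <- vapply(syms, function(s) mean(prior[[s]]), numeric(1))
  if (!is.null(tm$ordered)) {
    rng <- prior[[tm$ordered[1]]]
    times[tm$ordered[1]] <- rng[1] + 0.25 * diff(rng)
    times[tm$ordered[2]] <- rng[1] + 0.75 * diff(rng)
  }
  lin <- scenario_lineages(as.integer(sc))
  list(times = times, r1 = 0.5,
       N = setNames(rep(round(mean(prior$N)), length(lin)), lin),
       generation_time_years = prior$generation_time_years)
}

#' Simulate a pseudo-observed dataset (POD)
#'
#' Simulates one dataset under a known scenario and parameter vector, for
#' calibrating scenario recovery and interval coverage. The truth record
#' stores everything needed to score recovery.
#'
#' @param scenario_id integer in 1..6.
#' @param design a [study_design()].
#' @param theta parameter list; when `NULL`, drawn from `prior`.
#' @param prior a [prior_spec()].
#' @param seed optional integer seed.
#' @return list with `dataset` (a [snp_dataset()]) and `truth`
#'   (`scenario_id`, `theta`, `seed`).
#' @export
make_pod <- function(scenario_id, design, theta = NULL, prior = prior_spec(),
                     seed = NULL) {
  with_seed(seed, {
    if (is.null(theta)) theta <- draw_parameters(prior, scenario_id)
    scen <- build_scenario(scenario_id, theta, prior)
    ds <- simulate_snp_dataset(scen, design$samples, design$n_loci,
                               min_maf = design$min_maf)
    list(dataset = ds,
         truth = list(scenario_id = as.integer(scenario_id), theta = theta,
                      seed = seed))
  })
}

#' Generate a DArT CSV fixture with planted filter failures
#'
#' Builds a genotype table in which known numbers of loci fail each step of
#' the filtering cascade, so the expected number of survivors after every
#' step is computed by construction and emitted alongside the file. The
#' failure sets are disjoint: each planted locus fails exactly one step.
#' "Good" loci pass everything: reproducibility 1, full call rate,
#' polymorphic within each group, pooled MAF at or above `min_maf`.
#'
#' @param n_loci total loci (must cover the planted failures).
#' @param n_individuals total individuals, split into two equal groups
#'   `G1`/`G2`.
#' @param n_low_repro loci with reproducibility below 1.
#' @param n_low_callrate loci with one missing call.
#' @param n_monomorphic all-reference loci.
#' @param n_clone_dup loci duplicating the clone_id of a good locus (one of
#'   each pair is removed by secondary-SNP thinning).
#' @param min_maf MAF threshold the good loci are built to satisfy.
#' @param path output CSV path (default: a tempfile).
#' @param seed integer seed.
#' @return list with `path`, `groups` (individual/group table), and
#'   `expected`: a tibble of retained-locus counts after each cascade step.
#' @export
make_dart_fixture <- function(n_loci = 12, n_individuals = 8,
                              n_low_repro = 2, n_low_callrate = 2,
                              n_monomorphic = 2, n_clone_dup = 2,
                              min_maf = 0.05, path = tempfile(fileext = ".csv"),
                              seed = NULL) {
  n_planted <- n_low_repro + n_low_callrate + n_monomorphic + n_clone_dup
  if (n_planted >= n_loci)
    stop_validation("n_loci (%d) must exceed the planted failures (%d)",
                    n_loci, n_planted)
  if (n_individuals < 4 || n_individuals %% 2 != 0)
    stop_validation("n_individuals must be an even number >= 4")
  with_seed(seed, {
    g <- n_individuals / 2
    ids <- sprintf("ind%02d", seq_len(n_individuals))
    groups <- tibble(individual_id = ids,
                     group_label = rep(c("G1", "G2"), each = g))
    # one heterozygote per group at a random position: polymorphic in both
    # groups, pooled alt count 2 of 2*n_individuals copies
    good_locus <- function() {
      d <- integer(n_individuals)
      d[sample.int(g, 1)] <- 1L
      d[g + sample.int(g, 1)] <- 1L
      extra <- sample.int(n_individuals, sample(0:2, 1))
      d[extra] <- pmin(d[extra] + 1L, 2L)
      if (min(sum(d), 2 * n_individuals - sum(d)) / (2 * n_individuals) < min_maf)
        return(good_locus())
      d
    }
    dosages <- matrix(0L, nrow = n_individuals, ncol = n_loci)
    repro <- rep(1, n_loci)
    clone <- sprintf("C%04d", seq_len(n_loci))
    kind <- rep("good", n_loci)
    idx <- seq_len(n_loci)
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    i_repro <- take(n_low_repro)
    i_call <- take(n_low_callrate)
    i_mono <- take(n_monomorphic)
    i_dup <- take(n_clone_dup)
    i_good <- idx
    for (j in c(i_repro, i_call, i_dup, i_good)) dosages[, j] <- good_locus()
    repro[i_repro] <- 0.95
    kind[i_repro] <- "low_reproducibility"
    for (j in i_call) dosages[sample.int(n_individuals, 1), j] <- NA_integer_
    kind[i_call] <- "low_callrate"
    kind[i_mono] <- "monomorphic"
    clone[i_dup] <- clone[sample(i_good, n_clone_dup)]
    kind[i_dup] <- "clone_duplicate"
    loci <- tibble(locus_id = sprintf("L%04d", seq_len(n_loci)),
                   clone_id = clone, reproducibility = repro,
                   allele_ref = "A", allele_alt = "T")
    ds <- snp_dataset(dosages, loci, tibble(individual_id = ids))
    write_dart_csv(ds, path)
    expected <- tibble(
      step = c("input", "locus_quality", "individual_callrate", "monomorphic",
               "thin_secondary", "group_polymorphism", "maf"),
      retained_loci = as.integer(c(
        n_loci,
        n_loci - n_low_repro - n_low_callrate,
        n_loci - n_low_repro - n_low_callrate,
        n_loci - n_low_repro - n_low_callrate - n_monomorphic,
        n_loci - n_planted,
        n_loci - n_planted,
        n_loci - n_planted)))
    list(path = path, groups = groups, expected = expected,
         locus_kind = tibble(locus_id = loci$locus_id, kind = kind))
  })
}

#' Generate an aligned chloroplast-haplotype fixture
#'
#' Writes an aligned FASTA with two parental haplotype classes separated by
#' planted diagnostic differences (by default four SNPs plus one 4 bp and
#' one 6 bp indel, the 6 bp event an insertion present only in the PAM
#' class) and a hybrid cohort whose maternal classes are known. Optional
#' noise sites are polymorphic *within* a class and therefore never
#' diagnostic.
#'
#' @param n_pam,n_him numbers of parental reference sequences.
#' @param n_hyb_himtype,n_hyb_pamtype hybrids carrying the HIM / PAM
#'   chloroplast.
#' @param aln_length alignment length in bp (default 926, a typical
#'   intergenic-spacer read).
#' @param n_diag_snps number of diagnostic SNP columns.
#' @param indel_lengths lengths of the diagnostic indel events; the first is
#'   a deletion in the PAM class, the second an insertion present only in
#'   PAM (classes alternate for any further events).
#' @param n_noise noise columns (within-class polymorphisms) added to
#'   classes with at least two sequences.
#' @param path output FASTA path (default: a tempfile).
#' @param seed integer seed.
#' @return list with `path`, `alignment` (named character vector), `truth`
#'   (per-sequence class/role/locality tibble) and `diag_truth` (planted
#'   SNP columns and indel events).
#' @export
make_cpdna_fixture <- function(n_pam = 12, n_him = 1, n_hyb_himtype = 20,
                               n_hyb_pamtype = 2, aln_length = 926,
                               n_diag_snps = 4, indel_lengths = c(4, 6),
                               n_noise = 5, path = tempfile(fileext = ".fasta"),
                               seed = NULL) {
  if (n_pam < 1 || n_him < 1)
    stop_validation("need at least one reference sequence per parental class")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, aln_length, replace = TRUE)
    # reserve non-overlapping, non-adjacent column blocks for indels, then
    # diagnostic SNPs, then noise
    used <- logical(aln_length)
    pick_block <- function(len) {
      repeat {
        s <- sample.int(aln_length - len - 1, 1) + 1  # keep off the edges
        span <- s:(s + len - 1)
        guard <- max(1, s - 1):min(aln_length, s + len)
        if (!any(used[guard])) { used[guard] <<- TRUE; return(span) }
      }
    }
    indel_spans <- lapply(indel_lengths, pick_block)
    pick_col <- function() {
      repeat {
        s <- sample.int(aln_length, 1)
        if (!used[s]) { used[s] <<- TRUE; return(s) }
      }
    }
    snp_cols <- sort(vapply(seq_len(n_diag_snps), function(i) pick_col(),
                            numeric(1)))
    pam_hap <- anc
    him_hap <- anc
    snp_alleles <- lapply(snp_cols, function(col) {
      alt <- sample(setdiff(bases, anc[col]), 1)
      him_hap[col] <<- alt
      c(pam = anc[col], him = alt)
    })
    for (i in seq_along(indel_spans)) {
      span <- indel_spans[[i]]
      if (i %% 2 == 1) pam_hap[span] <- "-"   # deletion in PAM
      else him_hap[span] <- "-"               # insertion only in PAM
    }
    n_hyb <- n_hyb_himtype + n_hyb_pamtype
    seqs <- c(replicate(n_pam, pam_hap, simplify = FALSE),
              replicate(n_him, him_hap, simplify = FALSE),
              replicate(n_hyb_himtype, him_hap, simplify = FALSE),
              replicate(n_hyb_pamtype, pam_hap, simplify = FALSE))
    ids <- c(sprintf("PAM_%02d", seq_len(n_pam)),
             sprintf("HIM_%02d", seq_len(n_him)),
             sprintf("HYB_%02d", seq_len(n_hyb)))
    class_of <- c(rep("PAM", n_pam), rep("HIM", n_him),
                  rep("HIM", n_hyb_himtype), rep("PAM", n_hyb_pamtype))
    role <- c(rep("parent", n_pam + n_him), rep("hybrid", n_hyb))
    # noise columns are polymorphic within a class and must never alter the
    # parental panel's fixed differences: with >= 2 parents, mutate a proper
    # non-empty subset of the parents; with a lone parent (e.g. one herbarium
    # specimen) leave the parents alone and mutate hybrids of that class
    noise_classes <- c(if (n_pam >= 2 || n_hyb_pamtype >= 1) "PAM",
                       if (n_him >= 2 || n_hyb_himtype >= 1) "HIM")
    if (length(noise_classes) > 0 && n_noise > 0) {
      for (k in seq_len(n_noise)) {
        col <- pick_col()
        cl <- sample(noise_classes, 1)
        par_members <- which(class_of == cl & role == "parent")
        m <- if (length(par_members) >= 2)
          sample(par_members, sample.int(length(par_members) - 1, 1))
        else {
          hyb_members <- which(class_of == cl & role == "hybrid")
          sample(hyb_members, sample.int(length(hyb_members), 1))
        }
        for (j in m)
          seqs[[j]][col] <- sample(setdiff(bases, seqs[[j]][col]), 1)
      }
    }
    # hybrid localities: PAM-maternal hybrids in two distinct localities
    n_loc <- max(4, ceiling(n_hyb / 4))
    locality <- c(rep(NA_character_, n_pam + n_him),
                  sprintf("loc%02d", 1 + (seq_len(n_hyb_himtype) %% (n_loc - 2))),
                  sprintf("loc%02d", n_loc - seq_len(n_hyb_pamtype) %% 2))
    aln <- vapply(seqs, paste, character(1), collapse = "")
    names(aln) <- ids
    write_fasta_alignment(aln, path)
    list(path = path, alignment = aln,
         truth = tibble(seq_id = ids, class = class_of, role = role,
                        locality = locality),
         diag_truth = list(snp_cols = snp_cols,
                           snp_alleles = snp_alleles,
                           indel_spans = indel_spans,
                           indel_lengths = indel_lengths))
  })
}
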
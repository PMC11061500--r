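#' Read / write an aligned haplotype FASTA
#'
#' Sequences must be pre-aligned (uniform length); the alphabet is
#' `A/C/G/T/N/-`. Concatenated multi-marker alignments are supported as-is:
#' positions are just alignment columns, so a partition offset is only a
#' bookkeeping convention for the caller.
#'
#' @param path FASTA file path.
#' @return named character vector of aligned sequences (upper case).
#' @export
read_haplotype_alignment <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  aln <- toupper(as.character(ss))
  names(aln) <- sub("\\s.*$", "", names(ss))
  check_alignment(aln)
  aln
}

#' @rdname read_haplotype_alignment
#' @param aln named character vector of aligned sequences.
#' @export
write_fasta_alignment <- function(aln, path) {
  check_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), path)
  invisible(path)
}

check_alignment <- function(aln) {
  if (length(aln) == 0) stop_validation("empty alignment")
  if (length(unique(nchar(aln))) != 1)
    stop_validation("sequences are not aligned: unequal lengths")
  bad <- grepl("[^ACGTN-]", aln)
  if (any(bad))
    stop_validation("sequence %s contains characters outside A/C/G/T/N/-",
                    names(aln)[which(bad)[1]] %||% which(bad)[1])
  invisible(aln)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

#' Find fixed diagnostic differences between two haplotype classes
#'
#' A column is a diagnostic SNP when every class-A sequence carries one base
#' and every class-B sequence a different base, with no gaps or Ns in either
#' class at that column. Diagnostic indels are maximal runs of consecutive
#' columns where one class is entirely gapped and the other entirely
#' ungapped; each run is one event regardless of length. Columns that are
#' polymorphic within a class are skipped (not diagnostic). The result is
#' symmetric under swapping the class labels.
#'
#' @param aln named character vector of aligned sequences (see
#'   [read_haplotype_alignment()]).
#' @param class_a_ids,class_b_ids sequence ids of the two reference classes.
#' @param labels length-2 character, names reported for the classes.
#' @return a `diagnostic_set`: list with `snp_sites`
#'   (`column`, `allele_a`, `allele_b`), `indel_events`
#'   (`start`, `length`, `present_in` — the class whose sequences carry
#'   bases in the run) and `labels`.
#' @export
find_diagnostics <- function(aln, class_a_ids, class_b_ids,
                             labels = c("A", "B")) {
  check_alignment(aln)
  if (length(class_a_ids) < 1 || length(class_b_ids) < 1)
    stop_validation("need at least one sequence per class")
  missing_ids <- setdiff(c(class_a_ids, class_b_ids), names(aln))
  if (length(missing_ids) > 0)
    stop_validation("sequence id(s) not in the alignment: %s",
                    paste(missing_ids, collapse = ", "))
  m <- aln_matrix(aln)
  A <- m[class_a_ids, , drop = FALSE]
  B <- m[class_b_ids, , drop = FALSE]
  mono <- function(x) {  # the single shared state of a column, else NA
    u <- unique(x)
    if (length(u) == 1) u else NA_character_
  }
  a_state <- apply(A, 2, mono)
  b_state <- apply(B, 2, mono)
  bases <- c("A", "C", "G", "T")
  is_snp <- !is.na(a_state) & !is.na(b_state) &
    a_state %in% bases & b_state %in% bases & a_state != b_state
  snp_sites <- tibble(column = which(is_snp),
                      allele_a = a_state[is_snp],
                      allele_b = b_state[is_snp])
  a_gap <- !is.na(a_state) & a_state == "-" & !is.na(b_state) & b_state %in% bases
  b_gap <- !is.na(b_state) & b_state == "-" & !is.na(a_state) & a_state %in% bases
  runs <- function(flag, present_in) {
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble(start = starts[r$values], length = r$lengths[r$values],
           present_in = present_in)
  }
  found <- c(list(runs(a_gap, labels[2])), list(runs(b_gap, labels[1])))
  found <- found[!vapply(found, is.null, logical(1))]
  indel_events <- if (length(found) > 0)
    dplyr::arrange(dplyr::bind_rows(found), .data$start)
  else tibble(start = integer(), length = integer(), present_in = character())
  structure(list(snp_sites = snp_sites, indel_events = indel_events,
                 labels = setNames(labels, c("a", "b"))),
            class = "diagnostic_set")
}

#' @export
print.diagnostic_set <- function(x, ...) {
  cat(sprintf("<diagnostic_set> %s vs %s: %d diagnostic SNP(s), %d indel event(s)\n",
              x$labels["a"], x$labels["b"], nrow(x$snp_sites),
              nrow(x$indel_events)))
  if (nrow(x$indel_events) > 0)
    cat("indel lengths:", paste(x$indel_events$length, collapse = ", "), "\n")
  invisible(x)
}

# Score one aligned sequence against every diagnostic event.
# Returns a tibble with one row per event: event type, vote (class label or
# NA when unscorable).
score_events <- function(seq_chars, diag) {
  votes <- list()
  for (i in seq_len(nrow(diag$snp_sites))) {
    s <- diag$snp_sites[i, ]
    obs <- seq_chars[s$column]
    vote <- if (obs == s$allele_a) diag$labels[["a"]]
            else if (obs == s$allele_b) diag$labels[["b"]]
            else NA_character_
    votes[[length(votes) + 1]] <-
      tibble(event = sprintf("snp_%d", s$column), type = "snp", vote = vote)
  }
  for (i in seq_len(nrow(diag$indel_events))) {
    e <- diag$indel_events[i, ]
    span <- seq(e$start, e$start + e$length - 1)
    obs <- seq_chars[span]
    other <- setdiff(unname(diag$labels), e$present_in)
    vote <- if (all(obs %in% c("A", "C", "G", "T"))) e$present_in
            else if (all(obs == "-")) other
            else NA_character_
    votes[[length(votes) + 1]] <-
      tibble(event = sprintf("indel_%d_%dbp", e$start, e$length),
             type = "indel", vote = vote)
  }
  dplyr::bind_rows(votes)
}

#' Classify the maternal lineage of one sequence
#'
#' Majority vote over the scorable diagnostic events (each SNP and each
#' indel event counts one vote regardless of indel length). A site with `N`,
#' a gap at a SNP column, or a partially gapped indel span is unscorable and
#' counts against neither class. The call is `"ambiguous"` when fewer than
#' `min_sites` events are scorable or the vote is tied.
#'
#' @param seq one aligned sequence (character scalar, same coordinate system
#'   as the alignment the diagnostics came from).
#' @param diag a `diagnostic_set` from [find_diagnostics()].
#' @param min_sites minimum scorable events for a confident call.
#' @return list with `call` (a class label or `"ambiguous"`) and `votes`
#'   (per-event agreement tibble for audit).
#' @export
classify_maternal <- function(seq, diag, min_sites = 2) {
  stopifnot(inherits(diag, "diagnostic_set"))
  seq <- toupper(seq)
  v <- score_events(strsplit(seq, "")[[1]], diag)
  n_a <- sum(v$vote == diag$labels[["a"]], na.rm = TRUE)
  n_b <- sum(v$vote == diag$labels[["b"]], na.rm = TRUE)
  call <- if (n_a + n_b < min_sites || n_a == n_b) "ambiguous"
          else if (n_a > n_b) diag$labels[["a"]] else diag$labels[["b"]]
  list(call = call, votes = v, n_a = n_a, n_b = n_b)
}

#' Classify a cohort of sequences
#'
#' @param aln named character vector of aligned sequences.
#' @param diag a `diagnostic_set`.
#' @param ids sequences to classify (default: all).
#' @inheritParams classify_maternal
#' @return tibble with `seq_id`, `call`, and per-class vote counts `n_a`,
#'   `n_b`, `n_unscorable`.
#' @export
classify_cohort <- function(aln, diag, ids = NULL, min_sites = 2) {
  check_alignment(aln)
  if (is.null(ids)) ids <- names(aln)
  purrr::map_dfr(ids, function(id) {
    r <- classify_maternal(aln[[id]], diag, min_sites)
    tibble(seq_id = id, call = r$call, n_a = r$n_a, n_b = r$n_b,
           n_unscorable = sum(is.na(r$votes$vote)))
  })
}

#' Tabulate maternal directions per locality
#'
#' @param calls tibble with `seq_id` and `call` (from [classify_cohort()]).
#' @param localities tibble with `seq_id` and `locality`.
#' @return tibble of counts per locality and call, plus an `overall` row.
#' @export
summarize_directions <- function(calls, localities = NULL) {
  if (nrow(calls) == 0)
    return(tibble(locality = character(), call = character(), n = integer()))
  if (is.null(localities)) {
    localities <- tibble(seq_id = calls$seq_id, locality = "all")
  }
  joined <- dplyr::left_join(calls, localities, by = "seq_id")
  per_loc <- dplyr::count(joined, .data$locality, .data$call, name = "n")
  overall <- dplyr::count(joined, .data$call, name = "n")
  overall$locality <- "overall"
  dplyr::bind_rows(per_loc, overall[, c("locality", "call", "n")])
}
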
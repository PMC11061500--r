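#' Biallelic SNP dataset with per-locus metadata
#'
#' A `snp_dataset` bundles a diploid dosage matrix (individuals x loci,
#' entries 0/1/2 counting copies of the alternative allele, `NA` for missing
#' calls) with a locus metadata table and an individual table carrying group
#' labels. This is the in-memory form of a DArT-style genotype panel after
#' subsampling to the biallelic diploid format.
#'
#' The dosage orientation is taken from the input: the "alt" allele is
#' whatever the source file declares, never re-polarized.
#'
#' @param dosages integer matrix, individuals in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param loci tibble with columns `locus_id`, `clone_id`, `reproducibility`,
#'   `allele_ref`, `allele_alt`. `clone_id` groups secondary SNPs called from
#'   the same sequenced fragment.
#' @param individuals tibble with columns `individual_id` and `group`.
#'
#' @return A `snp_dataset` object.
#' @export
snp_dataset <- function(dosages, loci, individuals) {
  loci <- as_tibble(loci)
  individuals <- as_tibble(individuals)
  if (!all(c("locus_id", "clone_id", "reproducibility") %in% names(loci)))
    stop_validation("`loci` must have columns locus_id, clone_id, reproducibility")
  if (!"allele_ref" %in% names(loci)) loci$allele_ref <- "A"
  if (!"allele_alt" %in% names(loci)) loci$allele_alt <- "T"
  if (!"individual_id" %in% names(individuals))
    stop_validation("`individuals` must have a column individual_id")
  if (!"group" %in% names(individuals)) individuals$group <- NA_character_
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(individuals) || ncol(dosages) != nrow(loci))
    stop_validation(
      "dosage matrix is %d x %d but there are %d individuals and %d loci",
      nrow(dosages), ncol(dosages), nrow(individuals), nrow(loci))
  if (anyDuplicated(loci$locus_id))
    stop_validation("duplicated locus_id")
  if (anyDuplicated(individuals$individual_id))
    stop_validation("duplicated individual_id")
  if (any(is.na(loci$clone_id)) || any(!nzchar(loci$clone_id)))
    stop_validation("clone_id must be non-empty for every locus")
  bad_rep <- !is.na(loci$reproducibility) &
    (loci$reproducibility < 0 | loci$reproducibility > 1)
  if (any(bad_rep))
    stop_validation("reproducibility outside [0, 1] for locus %s",
                    loci$locus_id[which(bad_rep)[1]])
  bad <- which(!is.na(dosages) & !(dosages %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_validation("dosage outside {0, 1, 2, NA} at individual %s, locus %s",
                    individuals$individual_id[bad[1, 1]], loci$locus_id[bad[1, 2]])
  rownames(dosages) <- individuals$individual_id
  colnames(dosages) <- loci$locus_id
  structure(list(dosages = dosages, loci = loci, individuals = individuals),
            class = "snp_dataset")
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("<snp_dataset> %d individuals x %d loci\n",
              nrow(x$dosages), ncol(x$dosages)))
  grp <- table(x$individuals$group, useNA = "ifany")
  if (length(grp) > 0)
    cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.snp_dataset <- function(x) dim(x$dosages)

#' Number of individuals / loci in a dataset
#' @param ds a [snp_dataset()].
#' @return integer count.
#' @export
n_individuals <- function(ds) nrow(ds$dosages)

#' @rdname n_individuals
#' @export
n_loci <- function(ds) ncol(ds$dosages)

#' @export
as_tibble.snp_dataset <- function(x, ...) {
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(individual_id = x$individuals$individual_id,
                            group = x$individuals$group),
                     as_tibble(x$dosages)),
    cols = -c("individual_id", "group"),
    names_to = "locus_id", values_to = "dosage")
  dplyr::left_join(long, x$loci, by = "locus_id")
}

# Subset rows/columns keeping all three components aligned.
subset_snp_dataset <- function(ds, ind_keep = NULL, loc_keep = NULL) {
  if (is.null(ind_keep)) ind_keep <- seq_len(nrow(ds$dosages))
  if (is.null(loc_keep)) loc_keep <- seq_len(ncol(ds$dosages))
  snp_dataset(ds$dosages[ind_keep, loc_keep, drop = FALSE],
              ds$loci[loc_keep, , drop = FALSE],
              ds$individuals[ind_keep, , drop = FALSE])
}

#' Attach group labels to a dataset
#'
#' @param ds a [snp_dataset()].
#' @param groups two-column data frame `individual_id`, `group_label` (or
#'   `group`).
#' @return the dataset with its `individuals$group` column replaced.
#' @export
set_groups <- function(ds, groups) {
  groups <- as_tibble(groups)
  if ("group_label" %in% names(groups))
    groups <- dplyr::rename(groups, group = "group_label")
  if (!all(c("individual_id", "group") %in% names(groups)))
    stop_validation("`groups` needs columns individual_id and group_label/group")
  idx <- match(ds$individuals$individual_id, groups$individual_id)
  if (anyNA(idx))
    stop_validation("no group label for individual %s",
                    ds$individuals$individual_id[which(is.na(idx))[1]])
  ds$individuals$group <- groups$group[idx]
  ds
}

group_index <- function(ds, group) {
  idx <- which(ds$individuals$group %in% group)
  if (length(idx) == 0)
    stop_validation("no individuals in group '%s'", paste(group, collapse = "+"))
  idx
}

#' Read a DArT-style SNP CSV
#'
#' Expected dialect: one locus per row with leading columns `locus_id`,
#' `clone_id`, `reproducibility`, `allele_ref`, `allele_alt`, followed by one
#' column per individual holding dosages `0/1/2`, with missing calls written
#' as `NA`, `-` or an empty field. Unknown call symbols are mapped to missing
#' with a warning; a numeric call outside 0..2 is a validation error (it
#' indicates an unsubsampled polyploid genotype).
#'
#' @param path path to the CSV file.
#' @param groups optional `individual_id` / `group_label` table passed to
#'   [set_groups()].
#' @return a [snp_dataset()].
#' @export
read_dart_csv <- function(path, groups = NULL) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("locus_id", "clone_id", "reproducibility", "allele_ref", "allele_alt")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop_validation("malformed header: missing column(s) %s",
                    paste(missing_cols, collapse = ", "))
  ind_cols <- setdiff(names(raw), need)
  if (length(ind_cols) == 0)
    stop_validation("malformed header: no individual columns after %s",
                    paste(need, collapse = ", "))
  loci <- tibble(locus_id = raw$locus_id,
                 clone_id = raw$clone_id,
                 reproducibility = as.numeric(raw$reproducibility),
                 allele_ref = raw$allele_ref,
                 allele_alt = raw$allele_alt)
  calls <- as.matrix(raw[, ind_cols, drop = FALSE])
  is_missing <- is.na(calls) | calls %in% c("", "-", "–", "NA")
  parsed <- suppressWarnings(as.numeric(calls))
  bad_numeric <- !is_missing & !is.na(parsed) & !(parsed %in% 0:2)
  if (any(bad_numeric)) {
    at <- which(bad_numeric, arr.ind = TRUE)[1, ]
    stop_validation("dosage '%s' outside {0,1,2} at locus row %d, column '%s'",
                    calls[at[1], at[2]], at[1], ind_cols[at[2]])
  }
  unknown <- !is_missing & is.na(parsed)
  if (any(unknown)) {
    warn(sprintf("%d unrecognised call symbol(s) mapped to missing", sum(unknown)))
    is_missing <- is_missing | unknown
  }
  parsed[is_missing] <- NA_real_
  dosages <- t(matrix(as.integer(parsed), nrow = nrow(calls),
                      dimnames = list(NULL, ind_cols)))
  ds <- snp_dataset(dosages, loci, tibble(individual_id = ind_cols))
  if (!is.null(groups)) ds <- set_groups(ds, groups)
  ds
}

#' Write a DArT-style SNP CSV
#'
#' Emits the same dialect [read_dart_csv()] consumes (round-trip safe);
#' missing calls are written as `NA`.
#'
#' @param ds a [snp_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dart_csv <- function(ds, path) {
  meta <- ds$loci[, c("locus_id", "clone_id", "reproducibility",
                      "allele_ref", "allele_alt")]
  calls <- as.data.frame(t(ds$dosages))
  names(calls) <- ds$individuals$individual_id
  utils::write.csv(cbind(as.data.frame(meta), calls), path, row.names = FALSE)
  invisible(path)
}
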
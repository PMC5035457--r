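#' Read a secretome quantification table
#'
#' @param path TSV with columns `protein_id`, `ratio` (mutant/wild-type
#'   abundance ratio, > 0), `has_signal` (logical) and optionally
#'   `functional_tag`.
#' @return Tibble.
#' @export
read_secretome <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

check_secretome <- function(table) {
  table <- as_tibble(table)
  stopifnot(all(c("protein_id", "ratio", "has_signal") %in% names(table)))
  if (anyDuplicated(table$protein_id)) {
    stop("duplicate protein_id in secretome table", call. = FALSE)
  }
  if (any(!is.finite(table$ratio)) || any(table$ratio <= 0)) {
    stop("secretome ratios must be positive", call. = FALSE)
  }
  table
}

#' Differential protein secretion
#'
#' Labels each protein by its abundance ratio: `up` when
#' `ratio >= fold_threshold`, `down` when `ratio <= 1/fold_threshold`
#' (both boundaries inclusive), otherwise `unchanged`.
#'
#' @param table Secretome tibble (`protein_id`, `ratio`, `has_signal`).
#' @param fold_threshold Fold-change cut-off (default 2).
#' @return The table with a `direction` column added.
#' @export
differential_secretion <- function(table, fold_threshold = 2) {
  table <- check_secretome(table)
  stopifnot(fold_threshold > 1)
  table$direction <- dplyr::case_when(
    table$ratio >= fold_threshold ~ "up",
    table$ratio <= 1 / fold_threshold ~ "down",
    TRUE ~ "unchanged"
  )
  table
}

#' Fraction of secreted proteins lacking a secretion signal
#'
#' @param table Secretome tibble with a logical `has_signal` column.
#' @return Fraction in \[0, 1\].
#' @export
signal_fraction <- function(table) {
  table <- check_secretome(table)
  if (nrow(table) == 0L) stop("empty secretome table", call. = FALSE)
  mean(!table$has_signal)
}

#' Transcriptome/secretome concordance
#'
#' Joins protein-level and transcript-level calls on the shared gene id
#' namespace and labels each id: `concordant` (changed in the same direction
#' at both levels), `discordant` (opposite directions), `protein_only`,
#' `transcript_only`, or `unchanged`.
#'
#' @param secretome Output of [differential_secretion()].
#' @param de A `de_result` (or tibble with `gene_id`, `M`).
#' @param lfc log2 fold-change magnitude defining a transcript-level change
#'   (default 1).
#' @return Tibble: `protein_id`, `protein_direction`,
#'   `transcript_direction`, `concordance`.
#' @export
omics_concordance <- function(secretome, de, lfc = 1) {
  if (!"direction" %in% names(secretome)) {
    secretome <- differential_secretion(secretome)
  }
  de_tbl <- tibble(protein_id = de$gene_id,
                   transcript_direction = dplyr::case_when(
                     de$M >= lfc ~ "up",
                     de$M <= -lfc ~ "down",
                     TRUE ~ "unchanged"))
  out <- secretome |>
    dplyr::select("protein_id", protein_direction = "direction") |>
    dplyr::left_join(de_tbl, by = "protein_id")
  out$transcript_direction[is.na(out$transcript_direction)] <- "unchanged"
  out$concordance <- dplyr::case_when(
    out$protein_direction != "unchanged" &
      out$protein_direction == out$transcript_direction ~ "concordant",
    out$protein_direction != "unchanged" &
      out$transcript_direction != "unchanged" ~ "discordant",
    out$protein_direction != "unchanged" ~ "protein_only",
    out$transcript_direction != "unchanged" ~ "transcript_only",
    TRUE ~ "unchanged"
  )
  out
}
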
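CONSEQ_DAMAGING <- c("missense", "stop_gain", "stop_loss", "start_loss",
                     "frameshift")

#' Candidate-screen configuration
#'
#' Thresholds and inputs for the three candidate rules:
#' * Rule A — genes carrying a damaging CDS variant or a promoter/terminator
#'   window variant whose expression changes at least `2^lfc_a`-fold
#'   (fold change only, no probability condition);
#' * Rule B — transcription-factor genes with a damaging CDS variant;
#' * Rule C — transcription-factor genes called differentially expressed
#'   (`|M| >= lfc_c` and probability `>= prob_c`) without a qualifying CDS
#'   variant.
#'
#' @param tf_gene_ids Character vector of transcription-factor gene ids
#'   (may be empty).
#' @param lfc_a Rule-A |log2 fold change| threshold (default 1).
#' @param lfc_c Rule-C |log2 fold change| threshold (default 1).
#' @param prob_c Rule-C probability threshold (default 0.8).
#' @param window A [window_config()] (used when the pipeline annotates
#'   variants).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(tf_gene_ids = character(), lfc_a = 1, lfc_c = 1,
                          prob_c = 0.8, window = window_config()) {
  stopifnot(lfc_a >= 0, lfc_c >= 0, prob_c >= 0)
  structure(list(tf_gene_ids = as.character(tf_gene_ids), lfc_a = lfc_a,
                 lfc_c = lfc_c, prob_c = prob_c, window = window),
            class = "screen_config")
}

# per-gene variant evidence: damaging CDS variant or window flag
gene_variant_evidence <- function(annotated) {
  annotated |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      damaging_cds = any(.data$consequence %in% CONSEQ_DAMAGING),
      promoter = any(.data$promoter),
      terminator = any(.data$terminator),
      n_variants = dplyr::n_distinct(.data$variant_id),
      consequences = paste(
        sort(unique(.data$consequence[.data$consequence != "none"])),
        collapse = ","),
      aa_changes = paste(
        sort(unique(.data$aa_change[.data$aa_change != ""])), collapse = ","),
      .groups = "drop")
}

#' Rule A: variant-bearing genes with altered expression
#'
#' Genes having at least one variant with a damaging coding consequence
#' (missense, stop-gain, stop-loss, start-loss, frameshift) or a
#' promoter/terminator window flag, whose expression changes at least
#' `2^lfc_a`-fold (no probability condition).
#'
#' @param annotated Output of [annotate_variants()].
#' @param de A `de_result`.
#' @param config A [screen_config()].
#' @return Sorted character vector of gene ids.
#' @export
rule_a <- function(annotated, de, config = screen_config()) {
  ev <- gene_variant_evidence(annotated)
  with_variant <- ev$gene_id[ev$damaging_cds | ev$promoter | ev$terminator]
  altered <- de$gene_id[abs(de$M) >= config$lfc_a]
  sort(intersect(with_variant, altered))
}

#' Rule B: transcription factors with damaging CDS variants
#'
#' @param annotated Output of [annotate_variants()].
#' @param config A [screen_config()] supplying `tf_gene_ids`.
#' @return Sorted character vector of gene ids.
#' @export
rule_b <- function(annotated, config) {
  ev <- gene_variant_evidence(annotated)
  sort(intersect(ev$gene_id[ev$damaging_cds], config$tf_gene_ids))
}

#' Rule C: differentially expressed transcription factors
#'
#' Transcription-factor genes called DE at the Rule-C thresholds that do not
#' already carry a qualifying CDS variant (those are Rule B; genes meeting
#' both are reported with both memberships by [screen_candidates()]).
#'
#' @param de A `de_result`.
#' @param annotated Output of [annotate_variants()].
#' @param config A [screen_config()] supplying `tf_gene_ids`.
#' @return Sorted character vector of gene ids.
#' @export
rule_c <- function(de, annotated, config) {
  de_genes <- de$gene_id[abs(de$M) >= config$lfc_c &
                           de$probability >= config$prob_c]
  tf_de <- intersect(de_genes, config$tf_gene_ids)
  sort(setdiff(tf_de, rule_b(annotated, config)))
}

#' Screen for candidate regulator genes
#'
#' Runs the three evidence rules and returns their union with per-gene rule
#' provenance and the supporting evidence (consequences, window flags, M,
#' probability). Genes satisfying several rules carry all their tags.
#'
#' @param annotated Output of [annotate_variants()].
#' @param de A `de_result`.
#' @param config A [screen_config()].
#' @param concordance Optional output of [omics_concordance()]; when given,
#'   a `secretome_concordance` column is joined onto the candidates.
#' @param annotation Optional `genome_annotation`; candidates absent from it
#'   trigger an id-namespace warning but are retained.
#' @return A `candidate_screen` tibble ordered by `gene_id`, with the funnel
#'   report (per-rule counts) attached as an attribute (see [glance()]).
#' @export
screen_candidates <- function(annotated, de, config = screen_config(),
                              concordance = NULL, annotation = NULL) {
  a <- rule_a(annotated, de, config)
  b <- rule_b(annotated, config)
  cc <- rule_c(de, annotated, config)
  genes <- sort(unique(c(a, b, cc)))
  ev <- gene_variant_evidence(annotated)
  out <- tibble(gene_id = genes) |>
    dplyr::mutate(
      rule_a = .data$gene_id %in% a,
      rule_b = .data$gene_id %in% b,
      rule_c = .data$gene_id %in% cc,
      rules = purrr::pmap_chr(
        list(.data$rule_a, .data$rule_b, .data$rule_c),
        function(x, y, z) paste(c("A", "B", "C")[c(x, y, z)], collapse = ","))
    ) |>
    dplyr::left_join(ev, by = "gene_id") |>
    dplyr::left_join(
      tibble(gene_id = de$gene_id, M = de$M, probability = de$probability),
      by = "gene_id")
  out$n_variants[is.na(out$n_variants)] <- 0L
  out$damaging_cds[is.na(out$damaging_cds)] <- FALSE
  out$promoter[is.na(out$promoter)] <- FALSE
  out$terminator[is.na(out$terminator)] <- FALSE
  out$consequences[is.na(out$consequences)] <- ""
  out$aa_changes[is.na(out$aa_changes)] <- ""
  if (!is.null(concordance)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(concordance, gene_id = "protein_id",
                    secretome_concordance = "concordance"),
      by = "gene_id")
  }
  if (!is.null(annotation)) {
    unknown <- setdiff(genes, annotation$genes$gene_id)
    if (length(unknown)) {
      warning("candidate gene(s) unknown to the genome annotation: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  funnel <- tibble(
    rule = c("A", "B", "C", "total"),
    n_genes = c(length(a), length(b), length(cc), length(genes)))
  structure(out, class = c("candidate_screen", class(out)),
            funnel = funnel, config = config)
}

#' @exportS3Method generics::tidy
tidy.candidate_screen <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.candidate_screen <- function(x, ...) {
  f <- attr(x, "funnel")
  tibble(rule_a = f$n_genes[f$rule == "A"],
         rule_b = f$n_genes[f$rule == "B"],
         rule_c = f$n_genes[f$rule == "C"],
         total = f$n_genes[f$rule == "total"])
}

#' Funnel plot of a candidate screen
#'
#' Bar chart of the number of genes nominated by each rule and in total.
#'
#' @param object A `candidate_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.candidate_screen <- function(object, ...) {
  f <- attr(object, "funnel")
  f$rule <- factor(f$rule, levels = c("A", "B", "C", "total"))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$rule, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Evidence rule", y = "Candidate genes") +
    ggplot2::theme_minimal()
}

#' Write candidate-screen outputs
#'
#' @param candidates A `candidate_screen`.
#' @param tsv_path Candidate table TSV path (optional).
#' @param json_path Candidate list JSON path (optional).
#' @param funnel_path Funnel-report JSON path (optional).
#' @return `candidates`, invisibly.
#' @export
write_candidates <- function(candidates, tsv_path = NULL, json_path = NULL,
                             funnel_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(tidy(candidates), tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(tidy(candidates), json_path, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(funnel_path)) {
    jsonlite::write_json(attr(candidates, "funnel"), funnel_path,
                         digits = NA, pretty = TRUE)
  }
  invisible(candidates)
}

#' Read a transcription-factor gene list
#'
#' @param path Text file, one gene id per line (blank lines and `#` comments
#'   ignored).
#' @return Character vector.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
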
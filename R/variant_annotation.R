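#' Promoter/terminator window configuration
#'
#' Screening windows for potentially regulatory variants: a promoter window
#' upstream of the translation start (ATG) and a terminator window downstream
#' of the stop codon, both measured on the gene's coding orientation.
#'
#' @param upstream_bp Promoter window size in bp (default 1500).
#' @param downstream_bp Terminator window size in bp (default 200).
#' @return A list of class `window_config`.
#' @export
window_config <- function(upstream_bp = 1500L, downstream_bp = 200L) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "window_config")
}

# derive the variant class from ref/alt lengths and the VCF anchor convention
variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNV",
    nchar(ref) < nchar(alt) & startsWith(alt, ref) ~ "insertion",
    nchar(ref) > nchar(alt) & startsWith(ref, alt) ~ "deletion",
    TRUE ~ "other"
  )
}

# pure event coordinates (anchor removed): for deletions the removed span,
# for insertions the anchor base after which sequence is inserted
variant_event <- function(pos, ref, alt, vclass) {
  if (vclass == "SNV") {
    list(start = pos, end = pos + nchar(ref) - 1L, delta = 0L)
  } else if (vclass == "deletion") {
    list(start = pos + nchar(alt), end = pos + nchar(ref) - 1L,
         delta = nchar(alt) - nchar(ref))
  } else if (vclass == "insertion") {
    a <- pos + nchar(ref) - 1L
    list(start = a, end = a, delta = nchar(alt) - nchar(ref))
  } else {
    list(start = pos, end = pos + nchar(ref) - 1L, delta = 0L)
  }
}

#' Read variants from VCF
#'
#' Reads a VCF v4.x file, splits multi-allelic rows into one record per
#' alternate allele, validates each REF against the genome, and derives the
#' variant class (SNV, insertion, deletion, other).
#'
#' @param path Path to a VCF file.
#' @param annotation A `genome_annotation` providing the reference sequence.
#' @return Tibble with columns `variant_id`, `contig_id`, `pos`, `ref`,
#'   `alt`, `vclass`.
#' @export
read_variants <- function(path, annotation) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-row VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(variant_id = character(), contig_id = character(),
                  pos = integer(), ref = character(), alt = character(),
                  vclass = character()))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("malformed VCF row (non-numeric POS) at data line ",
         which(is.na(pos))[1], call. = FALSE)
  }
  v <- tibble(contig_id = fix$CHROM, pos = pos, ref = toupper(fix$REF),
              alt = toupper(fix$ALT)) |>
    tidyr::separate_longer_delim("alt", delim = ",")
  unknown <- setdiff(unique(v$contig_id), names(annotation$contigs))
  if (length(unknown)) {
    stop("VCF contig(s) absent from genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(v))) {
    contig <- annotation$contigs[[v$contig_id[i]]]
    span_end <- v$pos[i] + nchar(v$ref[i]) - 1L
    if (v$pos[i] < 1L || span_end > length(contig)) {
      stop("variant at ", v$contig_id[i], ":", v$pos[i],
           " outside contig bounds", call. = FALSE)
    }
    genome_ref <- as.character(Biostrings::subseq(contig, v$pos[i], span_end))
    if (genome_ref != v$ref[i]) {
      stop("REF mismatch at ", v$contig_id[i], ":", v$pos[i],
           " (VCF '", v$ref[i], "', genome '", genome_ref, "')", call. = FALSE)
    }
  }
  v$vclass <- variant_class(v$ref, v$alt)
  v$variant_id <- paste0(v$contig_id, ":", v$pos, ":", v$ref, ">", v$alt)
  dplyr::select(v, "variant_id", "contig_id", "pos", "ref", "alt", "vclass")
}

# genes whose CDS segments a variant's event touches (interior rule for
# insertions: the insertion point must fall strictly inside a segment)
cds_hits <- function(variant, annotation) {
  ev <- variant_event(variant$pos, variant$ref, variant$alt, variant$vclass)
  segs <- annotation$cds[annotation$cds$contig_id == variant$contig_id, ]
  if (variant$vclass == "insertion") {
    hit <- segs$start <= ev$start & ev$start + 1L <= segs$end
  } else {
    hit <- segs$start <= ev$end & ev$start <= segs$end
  }
  unique(segs$gene_id[hit])
}

#' Classify variants by genomic region
#'
#' Assigns each variant to exactly one of `CDS`, `intron` or `intergenic`,
#' with precedence CDS > intron > intergenic when genes overlap. A deletion
#' touching any CDS base is CDS; an insertion is inside a feature only when
#' its insertion point falls strictly between two bases of that feature.
#'
#' @param variants Variant tibble from [read_variants()].
#' @param annotation A `genome_annotation`.
#' @return The input tibble with a `region` column added.
#' @export
classify_region <- function(variants, annotation) {
  variants$region <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (length(cds_hits(v, annotation))) return("CDS")
    ev <- variant_event(v$pos, v$ref, v$alt, v$vclass)
    genes <- annotation$genes[annotation$genes$contig_id == v$contig_id, ]
    in_gene <- if (v$vclass == "insertion") {
      genes$start <= ev$start & ev$start + 1L <= genes$end
    } else {
      genes$start <= ev$end & ev$start <= genes$end
    }
    if (any(in_gene)) "intron" else "intergenic"
  }, character(1))
  variants
}

#' Coding consequences of variants
#'
#' For every variant whose event touches a CDS, determines the per-gene
#' coding consequence. SNVs are mapped strand-aware to their spliced-CDS
#' codon and re-translated: `synonymous`, `missense`, `stop_gain`,
#' `stop_loss` or `start_loss`, with an amino-acid change string such as
#' `"S725N"` (1-based protein position). InDels fully inside the CDS are
#' `frameshift` when the length change is not a multiple of 3, otherwise
#' `inframe_indel`; InDels spanning a CDS boundary are `frameshift` by
#' convention.
#'
#' @param variants Variant tibble.
#' @param annotation A `genome_annotation`.
#' @return Tibble with one row per variant x overlapped gene: `variant_id`,
#'   `gene_id`, `consequence`, `aa_change` (empty string for indels).
#' @export
coding_consequence <- function(variants, annotation) {
  cds_cache <- new.env(parent = emptyenv())
  get_cds <- function(gene_id) {
    if (is.null(cds_cache[[gene_id]])) {
      cds_cache[[gene_id]] <- spliced_cds(annotation, gene_id)
    }
    cds_cache[[gene_id]]
  }
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hits <- cds_hits(v, annotation)
    for (g in hits) {
      segs <- gene_segments(annotation, g)
      strand <- segs$strand[1]
      ev <- variant_event(v$pos, v$ref, v$alt, v$vclass)
      if (v$vclass == "SNV") {
        cpos <- genome_to_cds(annotation, g, v$pos)
        if (is.na(cpos)) next
        cds <- get_cds(g)
        if (nchar(cds) %% 3L != 0L) {
          warning("CDS of gene ", g, " not divisible by 3; ",
                  "consequence computed on the truncated frame", call. = FALSE)
        }
        codon_idx <- (cpos - 1L) %/% 3L + 1L
        if (codon_idx > nchar(cds) %/% 3L) next  # inside a trailing partial codon
        within <- (cpos - 1L) %% 3L + 1L
        codon <- substr(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
        alt_base <- if (strand == "-") {
          as.character(Biostrings::complement(Biostrings::DNAString(v$alt)))
        } else v$alt
        new_codon <- codon
        substr(new_codon, within, within) <- alt_base
        aa_of <- function(cod) {
          a <- unname(Biostrings::GENETIC_CODE[cod])
          if (is.na(a)) "X" else a
        }
        old_aa <- aa_of(codon)
        new_aa <- aa_of(new_codon)
        cons <- if (old_aa == new_aa) {
          "synonymous"
        } else if (codon_idx == 1L && codon == "ATG") {
          "start_loss"
        } else if (new_aa == "*" && old_aa != "*") {
          "stop_gain"
        } else if (old_aa == "*" && new_aa != "*") {
          "stop_loss"
        } else {
          "missense"
        }
        rows[[length(rows) + 1L]] <- tibble(
          variant_id = v$variant_id, gene_id = g, consequence = cons,
          aa_change = paste0(old_aa, codon_idx, new_aa))
      } else if (v$vclass %in% c("deletion", "insertion")) {
        inside <- if (v$vclass == "insertion") {
          any(segs$start <= ev$start & ev$start + 1L <= segs$end)
        } else {
          any(segs$start <= ev$start & ev$end <= segs$end)
        }
        cons <- if (!inside) {
          "frameshift"  # spans a CDS boundary: frameshift by convention
        } else if (abs(ev$delta) %% 3L != 0L) {
          "frameshift"
        } else {
          "inframe_indel"
        }
        rows[[length(rows) + 1L]] <- tibble(
          variant_id = v$variant_id, gene_id = g, consequence = cons,
          aa_change = "")
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(variant_id = character(), gene_id = character(),
                  consequence = character(), aa_change = character()))
  }
  dplyr::bind_rows(rows)
}

#' Apply a variant to the genome sequence
#'
#' Returns the genome with one edit applied (SNV substitution, deletion, or
#' insertion honouring the VCF anchor-base convention). Together with
#' [oracle_consequence()] this forms the brute-force mutate-and-retranslate
#' oracle used to validate the analytic consequence caller.
#'
#' @param contigs A named `DNAStringSet`.
#' @param variant One-row variant tibble (`contig_id`, `pos`, `ref`, `alt`,
#'   `vclass`).
#' @return A `DNAStringSet` with the edit applied.
#' @export
apply_variant <- function(contigs, variant) {
  seq <- as.character(contigs[[variant$contig_id]])
  n <- nchar(seq)
  ev <- variant_event(variant$pos, variant$ref, variant$alt, variant$vclass)
  if (ev$start < 1L || ev$end > n) stop("edit out of bounds", call. = FALSE)
  new_seq <- if (variant$vclass %in% c("SNV", "other")) {
    paste0(substr(seq, 1L, variant$pos - 1L), variant$alt,
           substr(seq, variant$pos + nchar(variant$ref), n))
  } else if (variant$vclass == "deletion") {
    paste0(substr(seq, 1L, ev$start - 1L), substr(seq, ev$end + 1L, n))
  } else {
    inserted <- substr(variant$alt, nchar(variant$ref) + 1L, nchar(variant$alt))
    paste0(substr(seq, 1L, ev$start), inserted, substr(seq, ev$start + 1L, n))
  }
  out <- as.character(contigs)
  out[[variant$contig_id]] <- new_seq
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(contigs)
  res
}

# shift a wild-type coordinate into mutant-genome coordinates
shift_coord <- function(p, ev, vclass, boundary = c("start", "end")) {
  boundary <- match.arg(boundary)
  if (vclass %in% c("SNV", "other")) return(p)
  if (vclass == "insertion") {
    return(if (p <= ev$start) p else p - ev$delta)  # delta > 0
  }
  # deletion
  len <- ev$end - ev$start + 1L
  if (p < ev$start) p
  else if (p > ev$end) p - len
  else if (boundary == "start") ev$start else ev$start - 1L
}

#' Brute-force consequence oracle
#'
#' Derives a variant's coding consequence for one gene independently of the
#' analytic caller: apply the edit to the genome, remap the gene's CDS
#' segments onto the mutated sequence, re-splice, re-translate, and compare
#' wild-type and mutant proteins.
#'
#' @param annotation A `genome_annotation`.
#' @param variant One-row variant tibble.
#' @param gene_id Gene to evaluate.
#' @return Consequence string (`synonymous`, `missense`, `stop_gain`,
#'   `stop_loss`, `start_loss`, `frameshift`, `inframe_indel`, or `none`
#'   when the edit leaves the spliced CDS untouched).
#' @export
oracle_consequence <- function(annotation, variant, gene_id) {
  segs <- gene_segments(annotation, gene_id)
  strand <- segs$strand[1]
  mut_contigs <- apply_variant(annotation$contigs, variant)
  ev <- variant_event(variant$pos, variant$ref, variant$alt, variant$vclass)
  new_segs <- segs
  new_segs$start <- vapply(segs$start, shift_coord, integer(1),
                           ev = ev, vclass = variant$vclass, boundary = "start")
  new_segs$end <- vapply(segs$end, shift_coord, integer(1),
                         ev = ev, vclass = variant$vclass, boundary = "end")
  # insertions interior to a segment lengthen it
  if (variant$vclass == "insertion") {
    interior <- segs$start <= ev$start & ev$start + 1L <= segs$end
    new_segs$end[interior] <- new_segs$end[interior] + ev$delta
  }
  new_segs <- new_segs[new_segs$end >= new_segs$start, ]
  contig <- mut_contigs[[variant$contig_id]]
  parts <- vapply(seq_len(nrow(new_segs)), function(i) {
    as.character(Biostrings::subseq(contig, new_segs$start[i], new_segs$end[i]))
  }, character(1))
  mut_cds <- paste(parts, collapse = "")
  if (strand == "-") {
    mut_cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(mut_cds)))
  }
  wt_cds <- spliced_cds(annotation, gene_id)
  if (identical(wt_cds, mut_cds)) return("none")
  if (variant$vclass %in% c("deletion", "insertion")) {
    delta <- nchar(mut_cds) - nchar(wt_cds)
    return(if (abs(delta) %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  wt_prot <- translate_cds(wt_cds)
  mut_prot <- translate_cds(mut_cds)
  if (identical(wt_prot, mut_prot)) return("synonymous")
  if (substr(wt_prot, 1L, 1L) == "M" && substr(mut_prot, 1L, 1L) != "M") {
    return("start_loss")
  }
  if (nchar(mut_prot) < nchar(wt_prot)) return("stop_gain")
  if (nchar(mut_prot) > nchar(wt_prot)) return("stop_loss")
  "missense"
}

# per-gene translation start and stop-codon-end genomic coordinates
gene_anchors <- function(annotation) {
  annotation$cds |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      contig_id = dplyr::first(.data$contig_id),
      strand = dplyr::first(.data$strand),
      tss = ifelse(dplyr::first(.data$strand) == "+",
                   min(.data$start), max(.data$end)),
      stop_end = ifelse(dplyr::first(.data$strand) == "+",
                        max(.data$end), min(.data$start)),
      .groups = "drop")
}

#' Flag variants in promoter/terminator windows
#'
#' A variant flags a gene's promoter when it lies strictly upstream of the
#' gene's translation start (first base of the ATG, strand-aware) within
#' `upstream_bp`; it flags the terminator when strictly downstream of the
#' last base of the stop codon within `downstream_bp`. One variant may flag
#' several genes. By default variants classified as CDS receive no window
#' flags.
#'
#' @param variants Variant tibble (a `region` column is added if absent).
#' @param annotation A `genome_annotation`.
#' @param window A [window_config()].
#' @param exclude_cds Drop window flags for variants inside any CDS
#'   (default `TRUE`).
#' @return Long tibble: `variant_id`, `gene_id`, `flag`
#'   (`"promoter"`/`"terminator"`).
#' @export
regulatory_flags <- function(variants, annotation, window = window_config(),
                             exclude_cds = TRUE) {
  if (!"region" %in% names(variants)) {
    variants <- classify_region(variants, annotation)
  }
  anchors <- gene_anchors(annotation)
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (exclude_cds && v$region == "CDS") next
    p <- variant_event(v$pos, v$ref, v$alt, v$vclass)$start
    a <- anchors[anchors$contig_id == v$contig_id, ]
    if (nrow(a) == 0L) next
    up_dist <- ifelse(a$strand == "+", a$tss - p, p - a$tss)
    down_dist <- ifelse(a$strand == "+", p - a$stop_end, a$stop_end - p)
    prom <- up_dist >= 1L & up_dist <= window$upstream_bp
    term <- down_dist >= 1L & down_dist <= window$downstream_bp
    if (any(prom)) {
      out[[length(out) + 1L]] <- tibble(
        variant_id = v$variant_id, gene_id = a$gene_id[prom], flag = "promoter")
    }
    if (any(term)) {
      out[[length(out) + 1L]] <- tibble(
        variant_id = v$variant_id, gene_id = a$gene_id[term], flag = "terminator")
    }
  }
  if (length(out) == 0L) {
    return(tibble(variant_id = character(), gene_id = character(),
                  flag = character()))
  }
  dplyr::bind_rows(out)
}

#' Annotate variants end to end
#'
#' Combines [classify_region()], [coding_consequence()] and
#' [regulatory_flags()] into the long per-variant, per-gene annotation table
#' used by the candidate screen.
#'
#' @param variants Variant tibble from [read_variants()].
#' @param annotation A `genome_annotation`.
#' @param window A [window_config()].
#' @param exclude_cds_windows Passed to [regulatory_flags()] as
#'   `exclude_cds`.
#' @return Tibble with one row per variant x gene association (variants with
#'   no associated gene keep a single row with `gene_id = NA`): columns
#'   `variant_id`, `contig_id`, `pos`, `ref`, `alt`, `vclass`, `region`,
#'   `gene_id`, `consequence`, `aa_change`, `promoter`, `terminator`.
#' @export
annotate_variants <- function(variants, annotation, window = window_config(),
                              exclude_cds_windows = TRUE) {
  variants <- classify_region(variants, annotation)
  coding <- coding_consequence(variants, annotation)
  flags <- regulatory_flags(variants, annotation, window,
                            exclude_cds = exclude_cds_windows)
  flags_wide <- if (nrow(flags)) {
    flags |>
      dplyr::mutate(value = TRUE) |>
      tidyr::pivot_wider(names_from = "flag", values_from = "value",
                         values_fill = FALSE)
  } else {
    tibble(variant_id = character(), gene_id = character())
  }
  for (col in c("promoter", "terminator")) {
    if (!col %in% names(flags_wide)) {
      flags_wide[[col]] <- logical(nrow(flags_wide))
    }
  }
  hits <- dplyr::full_join(coding, flags_wide, by = c("variant_id", "gene_id"))
  hits$consequence[is.na(hits$consequence)] <- "none"
  hits$aa_change[is.na(hits$aa_change)] <- ""
  hits$promoter[is.na(hits$promoter)] <- FALSE
  hits$terminator[is.na(hits$terminator)] <- FALSE
  out <- dplyr::left_join(variants, hits, by = "variant_id")
  out$consequence[is.na(out$consequence)] <- "none"
  out$aa_change[is.na(out$aa_change)] <- ""
  out$promoter[is.na(out$promoter)] <- FALSE
  out$terminator[is.na(out$terminator)] <- FALSE
  dplyr::arrange(out, .data$contig_id, .data$pos, .data$variant_id,
                 .data$gene_id)
}

#' Summarise annotated variants
#'
#' Category counts in the style of a variant-distribution figure: SNVs by
#' region (each SNV in exactly one region), InDels by class and in-CDS
#' status, non-synonymous SNVs, and promoter/terminator window SNVs.
#'
#' @param annotated Output of [annotate_variants()].
#' @return One-row tibble of counts.
#' @export
summarize_variants <- function(annotated) {
  per_variant <- annotated |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      vclass = dplyr::first(.data$vclass),
      region = dplyr::first(.data$region),
      nonsyn = any(.data$consequence %in%
                     c("missense", "stop_gain", "stop_loss", "start_loss")),
      promoter = any(.data$promoter),
      terminator = any(.data$terminator),
      .groups = "drop")
  snv <- per_variant[per_variant$vclass == "SNV", ]
  indel <- per_variant[per_variant$vclass %in% c("insertion", "deletion"), ]
  tibble(
    snv_total = nrow(snv),
    snv_cds = sum(snv$region == "CDS"),
    snv_intergenic = sum(snv$region == "intergenic"),
    snv_intron = sum(snv$region == "intron"),
    indel_total = nrow(indel),
    deletions = sum(indel$vclass == "deletion"),
    insertions = sum(indel$vclass == "insertion"),
    indels_in_cds = sum(indel$region == "CDS"),
    nonsynonymous_snvs = sum(snv$nonsyn),
    promoter_snvs = sum(snv$promoter),
    terminator_snvs = sum(snv$terminator)
  )
}

#' Write variants to VCF
#'
#' Minimal site-only VCF v4.2 writer (used by the synthetic-data generator).
#'
#' @param variants Variant tibble.
#' @param contigs A named `DNAStringSet` (for `##contig` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, contigs, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(contigs), ",length=",
           Biostrings::width(contigs), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  v <- dplyr::arrange(variants, .data$contig_id, .data$pos)
  rows <- paste(v$contig_id, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}
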
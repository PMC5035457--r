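#' Read a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file into a `DNAStringSet`, upper-casing the
#' sequence and validating it against the IUPAC DNA alphabet. RNA (`U`) is
#' rejected: the genome is expected as DNA.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per contig. Contig
#'   ids are the first whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(Biostrings::width(raw) == 0L)) {
    stop("zero-length sequence for contig(s): ",
         paste(ids[Biostrings::width(raw) == 0L], collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  # IUPAC DNA letters only; U (RNA) and anything else is a hard error.
  bad <- stringr::str_detect(seqs, "[^ACGTNRYSWKMBDHV]")
  if (any(bad)) {
    offending <- stringr::str_extract(seqs[bad][1], "[^ACGTNRYSWKMBDHV]")
    stop("non-IUPAC DNA character '", offending, "' in record '",
         ids[bad][1], "'", call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Construct a genome annotation
#'
#' Bundles contig sequences with strand-aware, possibly multi-exon gene
#' models and builds an interval index over gene spans and CDS segments.
#' Most users will obtain one from [read_gene_models()] or
#' [generate_scenario()] rather than calling this directly.
#'
#' @param contigs A named [Biostrings::DNAStringSet] of contig sequences.
#' @param genes Tibble with columns `gene_id`, `contig_id`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive genomic span) and
#'   optionally `biotype` (defaults to `"protein_coding"`).
#' @param cds Tibble with columns `gene_id`, `start`, `end`: the CDS segments
#'   of each gene in 1-based inclusive contig coordinates.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(contigs, genes, cds) {
  stopifnot(methods::is(contigs, "DNAStringSet"), !is.null(names(contigs)))
  genes <- as_tibble(genes)
  cds <- as_tibble(cds)
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  req <- c("gene_id", "contig_id", "strand", "start", "end")
  stopifnot(all(req %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(cds)))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in gene table", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  missing_contig <- setdiff(genes$contig_id, names(contigs))
  if (length(missing_contig)) {
    stop("gene contig_id(s) not in genome: ",
         paste(missing_contig, collapse = ", "), call. = FALSE)
  }
  cds <- dplyr::left_join(cds,
                          dplyr::select(genes, "gene_id", "contig_id", "strand"),
                          by = "gene_id")
  if (anyNA(cds$contig_id)) {
    stop("CDS segment(s) with unknown gene_id", call. = FALSE)
  }
  cds <- dplyr::arrange(cds, .data$gene_id, .data$start)
  clen <- setNames(Biostrings::width(contigs), names(contigs))
  if (any(cds$start < 1L | cds$end > clen[cds$contig_id] | cds$start > cds$end)) {
    stop("CDS segment outside contig bounds", call. = FALSE)
  }
  # non-overlap within each gene, and total length checks
  by_gene <- split(cds, cds$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)])) {
      stop("overlapping CDS segments in gene ", g$gene_id[1], call. = FALSE)
    }
    tot <- sum(g$end - g$start + 1L)
    if (tot < 3L) stop("total CDS length < 3 in gene ", g$gene_id[1], call. = FALSE)
    if (tot %% 3L != 0L) {
      warning("CDS length of gene ", g$gene_id[1],
              " is not divisible by 3 (", tot, " bp)", call. = FALSE)
    }
  }
  no_cds <- setdiff(genes$gene_id, cds$gene_id)
  if (length(no_cds)) {
    stop("gene(s) without CDS segments: ", paste(no_cds, collapse = ", "),
         call. = FALSE)
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id
  )
  cds_gr <- GenomicRanges::GRanges(
    seqnames = cds$contig_id,
    ranges = IRanges::IRanges(cds$start, cds$end),
    strand = cds$strand, gene_id = cds$gene_id
  )
  structure(
    list(contigs = contigs, genes = genes,
         cds = dplyr::select(cds, "gene_id", "contig_id", "strand", "start", "end"),
         gene_gr = gene_gr, cds_gr = cds_gr),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", length(x$contigs), " contig(s), ",
      nrow(x$genes), " gene(s), ", nrow(x$cds), " CDS segment(s)\n", sep = "")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`CDS` features from a GFF3 file into a
#' [genome_annotation()]. When a gene has several mRNA isoforms the first in
#' file order is retained (with a warning); genes without CDS are dropped as
#' non-coding.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param contigs Genome sequences from [read_genome_fasta()].
#' @return A `genome_annotation`.
#' @export
read_gene_models <- function(path, contigs) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  get_parent <- function(i) {
    p <- meta$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p)[1]
  }
  gene_idx <- which(type == "gene")
  genes <- tibble(
    gene_id = as.character(meta$ID[gene_idx]),
    contig_id = as.character(GenomicRanges::seqnames(gr)[gene_idx]),
    strand = as.character(GenomicRanges::strand(gr)[gene_idx]),
    start = GenomicRanges::start(gr)[gene_idx],
    end = GenomicRanges::end(gr)[gene_idx]
  )
  mrna_idx <- which(type == "mRNA")
  mrna <- tibble(
    mrna_id = as.character(meta$ID[mrna_idx]),
    gene_id = vapply(mrna_idx, get_parent, character(1))
  )
  if (anyNA(mrna$gene_id) || !all(mrna$gene_id %in% genes$gene_id)) {
    stop("mRNA with unresolvable gene parent", call. = FALSE)
  }
  multi <- unique(mrna$gene_id[duplicated(mrna$gene_id)])
  if (length(multi)) {
    warning("multiple mRNA isoforms for gene(s) ",
            paste(multi, collapse = ", "), "; first in file order retained",
            call. = FALSE)
  }
  kept_mrna <- mrna[!duplicated(mrna$gene_id), ]
  cds_idx <- which(type == "CDS")
  if (length(cds_idx) == 0L) stop("no CDS features in ", path, call. = FALSE)
  cds_strand <- as.character(GenomicRanges::strand(gr)[cds_idx])
  if (any(cds_strand %in% c("*", "."))) {
    stop("CDS feature with unknown strand", call. = FALSE)
  }
  cds_parent <- vapply(cds_idx, get_parent, character(1))
  if (anyNA(cds_parent)) stop("CDS feature without Parent attribute", call. = FALSE)
  # Parent may be an mRNA id or (minimal files) a gene id directly.
  parent_gene <- setNames(mrna$gene_id, mrna$mrna_id)[cds_parent]
  direct <- is.na(parent_gene) & cds_parent %in% genes$gene_id
  parent_gene[direct] <- cds_parent[direct]
  if (anyNA(parent_gene)) {
    stop("CDS with unresolvable parent: ",
         paste(unique(cds_parent[is.na(parent_gene)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- parent_gene %in% genes$gene_id &
    (cds_parent %in% kept_mrna$mrna_id | direct)
  cds <- tibble(
    gene_id = unname(parent_gene[keep]),
    start = GenomicRanges::start(gr)[cds_idx][keep],
    end = GenomicRanges::end(gr)[cds_idx][keep]
  )
  coding <- genes[genes$gene_id %in% cds$gene_id, ]
  genome_annotation(contigs, coding, cds)
}

# segments of one gene, sorted by start; errors on unknown id
gene_segments <- function(annotation, gene_id) {
  segs <- annotation$cds[annotation$cds$gene_id == gene_id, ]
  if (nrow(segs) == 0L) stop("unknown gene_id: ", gene_id, call. = FALSE)
  segs
}

#' Extract the spliced coding sequence of a gene
#'
#' Concatenates the CDS segments of a gene in 5' to 3' transcript order;
#' for minus-strand genes this is the reverse complement of the
#' ascending-coordinate concatenation.
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @return A character scalar: the coding sequence, starting at the annotated
#'   first codon.
#' @export
spliced_cds <- function(annotation, gene_id) {
  segs <- gene_segments(annotation, gene_id)
  contig <- annotation$contigs[[segs$contig_id[1]]]
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    as.character(Biostrings::subseq(contig, segs$start[i], segs$end[i]))
  }, character(1))
  seq <- paste(parts, collapse = "")
  if (segs$strand[1] == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  seq
}

#' Translate a coding sequence
#'
#' Standard genetic code (translation table 1). Translation stops at the
#' first stop codon, which is rendered as `"*"`; codons containing `N` or
#' other ambiguity codes translate to `"X"`. A trailing partial codon is
#' ignored.
#'
#' @param cds Character scalar, DNA of length >= 3.
#' @return Character scalar protein sequence.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon", call. = FALSE)
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1])]
  paste(aa, collapse = "")
}

# map a 1-based spliced-CDS coordinate to a genomic position (strand-aware)
cds_to_genome <- function(annotation, gene_id, cds_pos) {
  segs <- gene_segments(annotation, gene_id)
  widths <- segs$end - segs$start + 1L
  if (segs$strand[1] == "-") {
    segs <- segs[rev(seq_len(nrow(segs))), ]
    widths <- rev(widths)
  }
  cum <- cumsum(widths)
  vapply(cds_pos, function(p) {
    if (p < 1L || p > cum[length(cum)]) {
      stop("CDS position out of range for gene ", gene_id, call. = FALSE)
    }
    k <- which(p <= cum)[1]
    off <- p - (if (k == 1L) 0L else cum[k - 1L]) - 1L
    if (segs$strand[1] == "+") segs$start[k] + off else segs$end[k] - off
  }, integer(1))
}

# map a genomic position to a 1-based spliced-CDS coordinate (NA if not in CDS)
genome_to_cds <- function(annotation, gene_id, gpos) {
  segs <- gene_segments(annotation, gene_id)
  widths <- segs$end - segs$start + 1L
  ord <- if (segs$strand[1] == "-") rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
  segs <- segs[ord, ]
  widths <- widths[ord]
  before <- c(0L, cumsum(widths)[-length(widths)])
  vapply(gpos, function(p) {
    k <- which(p >= segs$start & p <= segs$end)
    if (length(k) == 0L) return(NA_integer_)
    k <- k[1]
    off <- if (segs$strand[1] == "+") p - segs$start[k] else segs$end[k] - p
    before[k] + off + 1L
  }, integer(1))
}

#' Features overlapping a genomic point
#'
#' Interval-index lookup of the gene spans and CDS segments overlapping one
#' position.
#'
#' @param annotation A `genome_annotation`.
#' @param contig_id Contig identifier.
#' @param pos 1-based position.
#' @return Tibble with columns `feature` (`"gene"` or `"cds"`) and `gene_id`.
#' @export
features_at <- function(annotation, contig_id, pos) {
  q <- GenomicRanges::GRanges(contig_id, IRanges::IRanges(pos, pos))
  gh <- GenomicRanges::findOverlaps(q, annotation$gene_gr, ignore.strand = TRUE)
  ch <- GenomicRanges::findOverlaps(q, annotation$cds_gr, ignore.strand = TRUE)
  dplyr::bind_rows(
    tibble(feature = "gene",
           gene_id = annotation$gene_gr$gene_id[S4Vectors::subjectHits(gh)]),
    tibble(feature = "cds",
           gene_id = annotation$cds_gr$gene_id[S4Vectors::subjectHits(ch)])
  )
}

#' Genome feature statistics
#'
#' Computes the classic one-row genome summary: assembly size, GC content of
#' the genome and of coding regions (N bases excluded from both GC
#' denominators), gene count, mean genomic gene span, and intron/exon
#' statistics derived from gaps between CDS segments.
#'
#' @param annotation A `genome_annotation`.
#' @return A one-row tibble with columns `genome_size_bp`, `gc_genome_pct`,
#'   `gene_count`, `gc_coding_pct`, `mean_gene_length_bp`,
#'   `mean_introns_per_gene`, `mean_intron_size_bp`, `mean_exon_size_bp`.
#'   Gene-dependent fields are `NA` when the annotation has no genes.
#' @export
genome_stats <- function(annotation) {
  gc_pct <- function(strings) {
    f <- Biostrings::letterFrequency(strings, c("A", "C", "G", "T"))
    tot <- colSums(f)
    100 * (tot[["C"]] + tot[["G"]]) / sum(tot)
  }
  genome_size <- sum(Biostrings::width(annotation$contigs))
  gc_genome <- gc_pct(annotation$contigs)
  n_genes <- nrow(annotation$genes)
  if (n_genes == 0L) {
    return(tibble(
      genome_size_bp = genome_size, gc_genome_pct = gc_genome,
      gene_count = 0L, gc_coding_pct = NA_real_,
      mean_gene_length_bp = NA_real_, mean_introns_per_gene = NA_real_,
      mean_intron_size_bp = NA_real_, mean_exon_size_bp = NA_real_
    ))
  }
  cds_seqs <- Biostrings::DNAStringSet(vapply(
    seq_len(nrow(annotation$cds)),
    function(i) as.character(Biostrings::subseq(
      annotation$contigs[[annotation$cds$contig_id[i]]],
      annotation$cds$start[i], annotation$cds$end[i])),
    character(1)))
  by_gene <- split(annotation$cds, annotation$cds$gene_id)
  intron_sizes <- unlist(lapply(by_gene, function(g) {
    if (nrow(g) < 2L) return(numeric(0))
    g$start[-1L] - g$end[-nrow(g)] - 1L
  }), use.names = FALSE)
  n_introns_per_gene <- vapply(by_gene, nrow, integer(1)) - 1L
  exon_sizes <- annotation$cds$end - annotation$cds$start + 1L
  tibble(
    genome_size_bp = genome_size,
    gc_genome_pct = gc_genome,
    gene_count = n_genes,
    gc_coding_pct = gc_pct(cds_seqs),
    mean_gene_length_bp = mean(annotation$genes$end - annotation$genes$start + 1L),
    mean_introns_per_gene = mean(n_introns_per_gene),
    mean_intron_size_bp = if (length(intron_sizes)) mean(intron_sizes) else NA_real_,
    mean_exon_size_bp = mean(exon_sizes)
  )
}

#' Write genome statistics
#'
#' Emits the [genome_stats()] row either as JSON or as a two-column
#' feature/value TSV shaped like a genome-features table.
#'
#' @param stats One-row tibble from [genome_stats()].
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genome_stats <- function(stats, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.list(stats), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    long <- tibble(feature = names(stats),
                   value = vapply(stats, function(v) format(v, digits = 10),
                                  character(1)))
    readr::write_tsv(long, path)
  }
  invisible(path)
}

#' Write contigs to FASTA
#'
#' @param contigs A named `DNAStringSet`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(contigs, path, width = 70L) {
  Biostrings::writeXStringSet(contigs, path, width = width)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` rows (one isoform per gene) with correct
#' CDS phases, readable back by [read_gene_models()].
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(annotation, path) {
  lines <- "##gff-version 3"
  genes <- dplyr::arrange(annotation$genes, .data$contig_id, .data$start)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    segs <- gene_segments(annotation, g$gene_id)
    lines <- c(lines,
      paste(g$contig_id, "regscreen", "gene", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$contig_id, "regscreen", "mRNA", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id), sep = "\t"))
    widths <- segs$end - segs$start + 1L
    ord <- if (g$strand == "-") rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
    before <- c(0L, cumsum(widths[ord])[-length(ord)])
    phase <- integer(nrow(segs))
    phase[ord] <- (3L - before %% 3L) %% 3L
    for (j in seq_len(nrow(segs))) {
      lines <- c(lines,
        paste(g$contig_id, "regscreen", "CDS", segs$start[j], segs$end[j], ".",
              g$strand, phase[j],
              paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id, ".t1"),
              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
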
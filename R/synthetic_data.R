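#' Scenario configuration for the synthetic-data generator
#'
#' Defines a fully self-contained toy study: a multi-contig genome with
#' strand-mixed multi-exon genes, a planted variant set covering every
#' consequence class, a two-strain count matrix with planted log2 effects,
#' a secretome table, a transcription-factor list and the intended
#' candidate sets for the three screen rules. The defaults mirror the shape
#' of the real study at toy scale: a 5/3/3 candidate funnel (11 genes),
#' variants across CDS/intron/intergenic regions and promoter/terminator
#' windows, 2 strains x 3 replicates, and a secretome in which 55% of
#' proteins lack a secretion signal.
#'
#' @param seed Integer seed; the whole bundle is deterministic given it.
#' @param n_contigs Number of contigs (default 3).
#' @param n_genes Number of protein-coding genes (default 120).
#' @param intron_range Min/max introns per gene (default 0-3).
#' @param minus_strand_prob Probability a gene lies on the minus strand.
#' @param codon_range Min/max codons per CDS (incl. start and stop).
#' @param intron_bp_range Min/max intron size in bp.
#' @param intergenic_bp_range Min/max intergenic gap in bp; the default
#'   (3300-3600) keeps promoter/terminator windows of neighbouring genes
#'   disjoint so planted window flags are unambiguous.
#' @param variant_plan Named integer vector of planted variant counts:
#'   `synonymous`, `missense`, `stop_gain`, `intron`, `intergenic`,
#'   `promoter`, `terminator`, `frameshift_deletion`, `insertion`.
#'   Rule-A and Rule-B genes receive their qualifying variants out of the
#'   `missense`/`promoter`/`terminator` budgets.
#' @param replicates Replicates per strain (default 3).
#' @param depth Median negative-binomial mean count per gene (default 1000).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2),
#'   default 0.02.
#' @param n_extra_de Background differentially expressed genes that are not
#'   candidates (default 8, half up at +2, half down at -2).
#' @param rule_a_lfc Planted log2 fold changes of the five Rule-A genes.
#' @param rule_c_lfc Planted log2 fold changes of the three Rule-C
#'   transcription factors.
#' @param n_tf_extra Transcription factors with neither variants nor
#'   expression change (default 6).
#' @param n_proteins,n_up,n_down Secretome size and planted up/down counts.
#' @param signal_fraction Fraction of secretome proteins carrying a
#'   secretion signal (default 0.45, i.e. 55% lack one).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_contigs = 3L,
                            n_genes = 120L,
                            intron_range = c(0L, 3L),
                            minus_strand_prob = 0.5,
                            codon_range = c(150L, 450L),
                            intron_bp_range = c(60L, 150L),
                            intergenic_bp_range = c(3300L, 3600L),
                            variant_plan = c(synonymous = 7L, missense = 12L,
                                             stop_gain = 2L, intron = 5L,
                                             intergenic = 20L, promoter = 8L,
                                             terminator = 3L,
                                             frameshift_deletion = 1L,
                                             insertion = 1L),
                            replicates = 3L,
                            depth = 1000,
                            dispersion = 0.02,
                            n_extra_de = 8L,
                            rule_a_lfc = c(2, 2, -2, -2, -2),
                            rule_c_lfc = c(-1.82, -1.82, 2),
                            n_tf_extra = 6L,
                            n_proteins = 60L,
                            n_up = 15L,
                            n_down = 10L,
                            signal_fraction = 0.45) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              n_genes = as.integer(n_genes), intron_range = intron_range,
              minus_strand_prob = minus_strand_prob,
              codon_range = codon_range, intron_bp_range = intron_bp_range,
              intergenic_bp_range = intergenic_bp_range,
              variant_plan = variant_plan, replicates = as.integer(replicates),
              depth = depth, dispersion = dispersion,
              n_extra_de = as.integer(n_extra_de), rule_a_lfc = rule_a_lfc,
              rule_c_lfc = rule_c_lfc, n_tf_extra = as.integer(n_tf_extra),
              n_proteins = as.integer(n_proteins), n_up = as.integer(n_up),
              n_down = as.integer(n_down), signal_fraction = signal_fraction)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  p <- cfg$variant_plan
  needed <- c("synonymous", "missense", "stop_gain", "intron", "intergenic",
              "promoter", "terminator", "frameshift_deletion", "insertion")
  if (!all(needed %in% names(p))) {
    stop("variant_plan must name counts for: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  n_rule_a <- length(cfg$rule_a_lfc)
  n_rule_c <- length(cfg$rule_c_lfc)
  # Rule-A genes draw 2 missense, 2 promoter, 1 terminator from the plan;
  # Rule-B genes draw 3 missense
  a_mis <- min(2L, n_rule_a)
  a_prom <- min(2L, max(0L, n_rule_a - 2L))
  a_term <- max(0L, n_rule_a - 4L)
  if (p[["missense"]] < a_mis + 3L || p[["promoter"]] < a_prom ||
      p[["terminator"]] < a_term) {
    stop("variant_plan too small for the planted candidate rules",
         call. = FALSE)
  }
  genes_needed <- sum(p[c("synonymous", "missense", "stop_gain", "intron",
                          "frameshift_deletion")]) +
    p[["promoter"]] + p[["terminator"]] + n_rule_c + cfg$n_tf_extra +
    cfg$n_extra_de
  if (genes_needed > cfg$n_genes) {
    stop("plan requires ", genes_needed, " genes but n_genes = ",
         cfg$n_genes, call. = FALSE)
  }
  if (cfg$n_up + cfg$n_down > cfg$n_proteins) {
    stop("secretome plan: n_up + n_down exceeds n_proteins", call. = FALSE)
  }
  if (cfg$n_proteins > cfg$n_genes) {
    stop("secretome plan: more proteins than genes", call. = FALSE)
  }
  invisible(cfg)
}

# codons of the standard code that do not encode stop
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

count_gc <- function(s) {
  sum(strsplit(s, "")[[1]] %in% c("G", "C"))
}

# build one gene: CDS split into exons with introns; returns the
# genomic-forward sequence and relative CDS segment coordinates
build_gene <- function(n_codons, n_introns, strand, intron_bp_range) {
  codons <- c("ATG", sample(sense_codons(), n_codons - 2L, replace = TRUE),
              sample(c("TAA", "TAG", "TGA"), 1L))
  cds <- paste(codons, collapse = "")
  L <- nchar(cds)
  cuts <- integer(0)
  if (n_introns > 0L) {
    repeat {
      cuts <- sort(sample(seq(30L, L - 30L), n_introns))
      if (n_introns == 1L || min(diff(cuts)) >= 30L) break
    }
  }
  bounds <- c(0L, cuts, L)
  exon_seqs <- vapply(seq_len(length(bounds) - 1L), function(k) {
    substr(cds, bounds[k] + 1L, bounds[k + 1L])
  }, character(1))
  intron_seqs <- if (n_introns > 0L) {
    vapply(seq_len(n_introns), function(k) {
      random_dna(sample(seq(intron_bp_range[1], intron_bp_range[2]), 1L))
    }, character(1))
  } else character(0)
  pieces <- character(0)
  for (k in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[k])
    if (k <= length(intron_seqs)) pieces <- c(pieces, intron_seqs[k])
  }
  tx_seq <- paste(pieces, collapse = "")
  # transcript-order relative exon intervals
  widths <- nchar(pieces)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  is_exon <- rep(c(TRUE, FALSE), length.out = length(pieces))
  rel <- tibble(start = starts[is_exon], end = ends[is_exon])
  total <- nchar(tx_seq)
  if (strand == "-") {
    fwd_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tx_seq)))
    rel <- tibble(start = total - rel$end + 1L, end = total - rel$start + 1L)
    rel <- rel[order(rel$start), ]
  } else {
    fwd_seq <- tx_seq
  }
  list(seq = fwd_seq, rel_segments = rel, length = total,
       exon_sizes = nchar(exon_seqs), intron_sizes = nchar(intron_seqs),
       cds_seq = cds)
}

# find a codon substitution of the requested consequence type; returns
# list(within, alt) or NULL
codon_substitution <- function(codon, type) {
  gc <- Biostrings::GENETIC_CODE
  old_aa <- unname(gc[codon])
  for (within in sample(1:3)) {
    for (alt in sample(setdiff(c("A", "C", "G", "T"),
                               substr(codon, within, within)))) {
      new_codon <- codon
      substr(new_codon, within, within) <- alt
      new_aa <- unname(gc[new_codon])
      ok <- switch(type,
        synonymous = new_aa == old_aa,
        missense = new_aa != old_aa && new_aa != "*" && old_aa != "*",
        stop_gain = new_aa == "*" && old_aa != "*")
      if (ok) return(list(within = within, alt = alt))
    }
  }
  NULL
}

#' Generate a synthetic screening scenario
#'
#' Builds the full fixture bundle in memory: genome and gene models, planted
#' variants (each coding variant verified against the mutate-and-retranslate
#' oracle at generation time), a two-strain negative-binomial count matrix
#' with planted log2 effects, a secretome table, a transcription-factor
#' list, and the truth manifest recording every planted label. Deterministic
#' given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list of class `screen_scenario` with elements `annotation`,
#'   `variants`, `counts`, `samples`, `lengths`, `secretome`, `tf_ids`,
#'   `truth` and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  validate_scenario_config(config)
  withr::with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(cfg) {
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  contig_ids <- sprintf("ctg%02d", seq_len(cfg$n_contigs))
  contig_of <- sort(rep_len(seq_len(cfg$n_contigs), cfg$n_genes))

  ## ---- genome assembly -------------------------------------------------
  contig_seqs <- setNames(vector("list", cfg$n_contigs), contig_ids)
  genes <- list()
  cds <- list()
  book <- list(exon_sizes = integer(0), intron_sizes = integer(0),
               introns_per_gene = integer(0), gene_spans = integer(0),
               gc_bases = 0, atcg_bases = 0)
  gene_info <- list()  # per-gene construction record
  for (ci in seq_len(cfg$n_contigs)) {
    pieces <- character(0)
    offset <- 0L
    for (gi in which(contig_of == ci)) {
      gap <- random_dna(sample(seq(cfg$intergenic_bp_range[1],
                                   cfg$intergenic_bp_range[2]), 1L))
      pieces <- c(pieces, gap)
      offset <- offset + nchar(gap)
      strand <- if (stats::runif(1) < cfg$minus_strand_prob) "-" else "+"
      n_codons <- sample(seq(cfg$codon_range[1], cfg$codon_range[2]), 1L)
      n_introns <- sample(seq(cfg$intron_range[1], cfg$intron_range[2]), 1L)
      g <- build_gene(n_codons, n_introns, strand, cfg$intron_bp_range)
      pieces <- c(pieces, g$seq)
      genes[[length(genes) + 1L]] <- tibble(
        gene_id = gene_ids[gi], contig_id = contig_ids[ci], strand = strand,
        start = offset + 1L, end = offset + g$length,
        biotype = "protein_coding")
      cds[[length(cds) + 1L]] <- tibble(
        gene_id = gene_ids[gi],
        start = offset + g$rel_segments$start,
        end = offset + g$rel_segments$end)
      gene_info[[gene_ids[gi]]] <- list(
        n_codons = n_codons, cds_len = 3L * n_codons, strand = strand,
        contig = contig_ids[ci])
      book$exon_sizes <- c(book$exon_sizes, g$exon_sizes)
      book$intron_sizes <- c(book$intron_sizes, g$intron_sizes)
      book$introns_per_gene <- c(book$introns_per_gene, n_introns)
      book$gene_spans <- c(book$gene_spans, g$length)
      offset <- offset + g$length
    }
    tail_gap <- random_dna(sample(seq(cfg$intergenic_bp_range[1],
                                      cfg$intergenic_bp_range[2]), 1L))
    pieces <- c(pieces, tail_gap)
    contig_seqs[[ci]] <- paste(pieces, collapse = "")
  }
  contigs <- Biostrings::DNAStringSet(unlist(contig_seqs))
  names(contigs) <- contig_ids
  for (s in as.character(contigs)) {
    book$gc_bases <- book$gc_bases + count_gc(s)
    book$atcg_bases <- book$atcg_bases + nchar(s)
  }
  annotation <- genome_annotation(contigs, dplyr::bind_rows(genes),
                                  dplyr::bind_rows(cds))

  ## ---- gene role assignment -------------------------------------------
  p <- cfg$variant_plan
  n_rule_a <- length(cfg$rule_a_lfc)
  n_rule_c <- length(cfg$rule_c_lfc)
  pool <- sample(gene_ids)  # shuffled; roles are disjoint
  take <- function(n) {
    if (n > length(pool)) stop("gene pool exhausted", call. = FALSE)
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  # Rule-A gene variant subtypes: 2 missense, 2 promoter, 1 terminator
  # (clipped for shorter rule_a_lfc vectors)
  a_sub <- rep(c("missense", "missense", "promoter", "promoter",
                 "terminator"), length.out = n_rule_a)
  roles <- list(
    rule_a = take(n_rule_a),
    rule_b = take(3L),
    rule_c = take(n_rule_c),
    tf_extra = take(cfg$n_tf_extra),
    extra_de = take(cfg$n_extra_de),
    synonymous = take(p[["synonymous"]]),
    missense = take(p[["missense"]] - sum(a_sub == "missense") - 3L),
    stop_gain = take(p[["stop_gain"]]),
    promoter = take(p[["promoter"]] - sum(a_sub == "promoter")),
    terminator = take(p[["terminator"]] - sum(a_sub == "terminator")),
    frameshift = take(p[["frameshift_deletion"]])
  )
  # intron variants need genes that actually have introns
  with_introns <- annotation$cds |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull(.data$gene_id)
  intron_pool <- intersect(pool, with_introns)
  if (length(intron_pool) < p[["intron"]]) {
    stop("not enough unassigned genes with introns for the intron plan",
         call. = FALSE)
  }
  roles$intron <- sample(intron_pool, p[["intron"]])
  pool <- setdiff(pool, roles$intron)
  tf_ids <- sort(c(roles$rule_b, roles$rule_c, roles$tf_extra))

  ## ---- variant planting ------------------------------------------------
  used <- new.env(parent = emptyenv())  # "<contig>:<pos>" occupancy
  mark_used <- function(contig, from, to) {
    for (q in seq(from - 1L, to + 1L)) {
      used[[paste0(contig, ":", q)]] <- TRUE
    }
  }
  is_free <- function(contig, from, to) {
    !any(vapply(seq(from - 1L, to + 1L), function(q) {
      isTRUE(used[[paste0(contig, ":", q)]])
    }, logical(1)))
  }
  used_codons <- new.env(parent = emptyenv())
  variants <- list()
  truth_variants <- list()
  add_variant <- function(contig, pos, ref, alt, category, region, gene = NA,
                          consequence = "none", promoter_of = "",
                          terminator_of = "") {
    vclass <- variant_class(ref, alt)
    vid <- paste0(contig, ":", pos, ":", ref, ">", alt)
    variants[[length(variants) + 1L]] <<- tibble(
      variant_id = vid, contig_id = contig, pos = pos, ref = ref, alt = alt,
      vclass = vclass)
    truth_variants[[length(truth_variants) + 1L]] <<- tibble(
      variant_id = vid, contig_id = contig, pos = pos, ref = ref, alt = alt,
      vclass = vclass, category = category, region = region,
      gene_id = as.character(gene), consequence = consequence,
      promoter_of = promoter_of, terminator_of = terminator_of)
  }
  genome_base <- function(contig, pos) {
    as.character(Biostrings::subseq(annotation$contigs[[contig]], pos, pos))
  }

  plant_coding_snv <- function(gene, type) {
    info <- gene_info[[gene]]
    wt_cds <- spliced_cds(annotation, gene)
    n_cod <- nchar(wt_cds) %/% 3L
    for (attempt in seq_len(200L)) {
      idx <- sample(seq(2L, n_cod - 1L), 1L)
      key <- paste0(gene, ":", idx)
      if (isTRUE(used_codons[[key]])) next
      codon <- substr(wt_cds, (idx - 1L) * 3L + 1L, idx * 3L)
      sub <- codon_substitution(codon, type)
      if (is.null(sub)) next
      cpos <- (idx - 1L) * 3L + sub$within
      gpos <- cds_to_genome(annotation, gene, cpos)
      if (!is_free(info$contig, gpos, gpos)) next
      ref <- genome_base(info$contig, gpos)
      alt <- if (info$strand == "-") {
        as.character(Biostrings::complement(Biostrings::DNAString(sub$alt)))
      } else sub$alt
      v <- tibble(variant_id = "x", contig_id = info$contig, pos = gpos,
                  ref = ref, alt = alt, vclass = "SNV")
      stopifnot(identical(oracle_consequence(annotation, v, gene), type))
      used_codons[[key]] <- TRUE
      mark_used(info$contig, gpos, gpos)
      gc_code <- Biostrings::GENETIC_CODE
      old_aa <- unname(gc_code[codon])
      new_codon <- codon
      substr(new_codon, sub$within, sub$within) <- sub$alt
      new_aa <- unname(gc_code[new_codon])
      add_variant(info$contig, gpos, ref, alt, category = type,
                  region = "CDS", gene = gene, consequence = type)
      return(invisible(paste0(old_aa, idx, new_aa)))
    }
    stop("could not plant a ", type, " SNV in gene ", gene, call. = FALSE)
  }

  plant_window_snv <- function(gene, side) {
    segs <- gene_segments(annotation, gene)
    strand <- segs$strand[1]
    contig <- segs$contig_id[1]
    for (attempt in seq_len(200L)) {
      if (side == "promoter") {
        d <- sample(seq(50L, 1400L), 1L)
        tss <- if (strand == "+") min(segs$start) else max(segs$end)
        pos <- if (strand == "+") tss - d else tss + d
      } else {
        d <- sample(seq(20L, 190L), 1L)
        stop_end <- if (strand == "+") max(segs$end) else min(segs$start)
        pos <- if (strand == "+") stop_end + d else stop_end - d
      }
      if (pos < 1L || pos > length(annotation$contigs[[contig]])) next
      if (!is_free(contig, pos, pos)) next
      ref <- genome_base(contig, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      mark_used(contig, pos, pos)
      add_variant(contig, pos, ref, alt, category = side,
                  region = "intergenic", gene = gene,
                  promoter_of = if (side == "promoter") gene else "",
                  terminator_of = if (side == "terminator") gene else "")
      return(invisible(pos))
    }
    stop("could not plant a ", side, " window SNV near gene ", gene,
         call. = FALSE)
  }

  intergenic_site <- function() {
    # a site > 1600 bp from every gene span: outside all windows
    for (attempt in seq_len(500L)) {
      contig <- sample(contig_ids, 1L)
      pos <- sample(length(annotation$contigs[[contig]]), 1L)
      g <- annotation$genes[annotation$genes$contig_id == contig, ]
      dist <- pmax(g$start - pos, pos - g$end)
      if (any(dist < 1601L)) next
      if (!is_free(contig, pos, pos)) next
      return(list(contig = contig, pos = pos))
    }
    stop("could not find a clean intergenic site", call. = FALSE)
  }

  # rule A and B coding/window variants first (they come out of the budgets)
  for (i in seq_len(n_rule_a)) {
    g <- roles$rule_a[i]
    if (a_sub[i] %in% c("missense")) plant_coding_snv(g, "missense")
    else plant_window_snv(g, a_sub[i])
  }
  for (g in roles$rule_b) plant_coding_snv(g, "missense")
  for (g in roles$synonymous) plant_coding_snv(g, "synonymous")
  for (g in roles$missense) plant_coding_snv(g, "missense")
  for (g in roles$stop_gain) plant_coding_snv(g, "stop_gain")
  for (g in roles$promoter) plant_window_snv(g, "promoter")
  for (g in roles$terminator) plant_window_snv(g, "terminator")

  for (g in roles$intron) {
    segs <- gene_segments(annotation, g)
    gaps <- tibble(start = segs$end[-nrow(segs)] + 1L,
                   end = segs$start[-1L] - 1L)
    gaps <- gaps[gaps$end >= gaps$start + 2L, ]
    contig <- segs$contig_id[1]
    planted <- FALSE
    for (attempt in seq_len(100L)) {
      row <- gaps[sample(nrow(gaps), 1L), ]
      pos <- sample(seq(row$start + 1L, row$end - 1L), 1L)
      if (!is_free(contig, pos, pos)) next
      ref <- genome_base(contig, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      mark_used(contig, pos, pos)
      add_variant(contig, pos, ref, alt, category = "intron",
                  region = "intron", gene = g)
      planted <- TRUE
      break
    }
    if (!planted) stop("could not plant an intron SNV in gene ", g,
                       call. = FALSE)
  }

  for (g in roles$frameshift) {
    segs <- gene_segments(annotation, g)
    seg <- segs[which.max(segs$end - segs$start), ]
    pos <- sample(seq(seg$start + 5L, seg$end - 5L), 1L)
    contig <- seg$contig_id
    anchor <- pos - 1L
    ref <- paste0(genome_base(contig, anchor), genome_base(contig, pos))
    alt <- genome_base(contig, anchor)
    v <- tibble(variant_id = "x", contig_id = contig, pos = anchor,
                ref = ref, alt = alt, vclass = "deletion")
    stopifnot(identical(oracle_consequence(annotation, v, g), "frameshift"))
    mark_used(contig, anchor, pos)
    add_variant(contig, anchor, ref, alt, category = "frameshift_deletion",
                region = "CDS", gene = g, consequence = "frameshift")
  }

  for (i in seq_len(p[["intergenic"]])) {
    site <- intergenic_site()
    ref <- genome_base(site$contig, site$pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    mark_used(site$contig, site$pos, site$pos)
    add_variant(site$contig, site$pos, ref, alt, category = "intergenic",
                region = "intergenic")
  }

  for (i in seq_len(p[["insertion"]])) {
    site <- intergenic_site()
    ref <- genome_base(site$contig, site$pos)
    alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1L))
    mark_used(site$contig, site$pos, site$pos)
    add_variant(site$contig, site$pos, ref, alt, category = "insertion",
                region = "intergenic")
  }

  variants <- dplyr::bind_rows(variants) |>
    dplyr::arrange(.data$contig_id, .data$pos)
  truth_variants <- dplyr::bind_rows(truth_variants) |>
    dplyr::arrange(.data$contig_id, .data$pos)

  ## ---- expression plan -------------------------------------------------
  true_lfc <- setNames(rep(0, cfg$n_genes), gene_ids)
  true_lfc[roles$rule_a] <- cfg$rule_a_lfc
  true_lfc[roles$rule_c] <- cfg$rule_c_lfc
  if (cfg$n_extra_de > 0L) {
    true_lfc[roles$extra_de] <- rep(c(2, -2), length.out = cfg$n_extra_de)
  }
  base_mean <- setNames(
    stats::rlnorm(cfg$n_genes, meanlog = log(cfg$depth), sdlog = 0.7),
    gene_ids)
  # planted genes get fixed, well-expressed baselines; down-regulated ones
  # get more mass so the two library sizes stay close
  planted <- true_lfc != 0
  base_mean[planted & true_lfc > 0] <- cfg$depth
  base_mean[planted & true_lfc < 0] <- 2 * cfg$depth
  sample_ids <- c(paste0("wt_", seq_len(cfg$replicates)),
                  paste0("mut_", seq_len(cfg$replicates)))
  samples <- tibble(sample_id = sample_ids,
                    strain = rep(c("WT", "MUT"), each = cfg$replicates))
  size <- 1 / cfg$dispersion
  counts_mat <- matrix(0L, nrow = cfg$n_genes, ncol = length(sample_ids),
                       dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- if (samples$strain[j] == "MUT") base_mean * 2^true_lfc else base_mean
    counts_mat[, j] <- rnbinom(cfg$n_genes, size = size, mu = mu)
  }
  counts <- dplyr::bind_cols(tibble(gene_id = gene_ids),
                             as_tibble(counts_mat))
  lengths <- tibble(
    gene_id = gene_ids,
    length_bp = vapply(gene_ids, function(g) gene_info[[g]]$cds_len,
                       integer(1)))

  ## ---- secretome plan --------------------------------------------------
  extra_up <- roles$extra_de[true_lfc[roles$extra_de] > 0]
  extra_down <- roles$extra_de[true_lfc[roles$extra_de] < 0]
  other_pool <- setdiff(gene_ids, roles$extra_de)
  up_ids <- c(extra_up, sample(other_pool, cfg$n_up - length(extra_up)))
  other_pool <- setdiff(other_pool, up_ids)
  down_ids <- c(extra_down,
                sample(other_pool, cfg$n_down - length(extra_down)))
  other_pool <- setdiff(other_pool, down_ids)
  flat_ids <- sample(other_pool, cfg$n_proteins - cfg$n_up - cfg$n_down)
  prot_ids <- c(up_ids, down_ids, flat_ids)
  direction <- rep(c("up", "down", "unchanged"),
                   c(cfg$n_up, cfg$n_down, length(flat_ids)))
  ratio <- c(stats::runif(cfg$n_up, 2.2, 6),
             stats::runif(cfg$n_down, 0.15, 0.45),
             stats::runif(length(flat_ids), 0.67, 1.49))
  n_signal <- round(cfg$signal_fraction * cfg$n_proteins)
  has_signal <- sample(rep(c(TRUE, FALSE),
                           c(n_signal, cfg$n_proteins - n_signal)))
  secretome <- tibble(
    protein_id = prot_ids, ratio = ratio, has_signal = has_signal,
    functional_tag = sample(c("CBH", "EG", "BGL", "xylanase", "protease",
                              "transporter", "unknown"),
                            cfg$n_proteins, replace = TRUE)) |>
    dplyr::arrange(.data$protein_id)
  truth_secretome <- tibble(protein_id = prot_ids, direction = direction) |>
    dplyr::arrange(.data$protein_id)

  ## ---- truth manifest --------------------------------------------------
  candidates <- dplyr::bind_rows(
    tibble(gene_id = sort(roles$rule_a), rule = "A"),
    tibble(gene_id = sort(roles$rule_b), rule = "B"),
    tibble(gene_id = sort(roles$rule_c), rule = "C"))
  truth <- list(
    variants = truth_variants,
    genes = tibble(gene_id = gene_ids, true_lfc = unname(true_lfc),
                   base_mean = unname(base_mean),
                   planted_de = unname(abs(true_lfc) >= 1)),
    secretome = truth_secretome,
    candidates = candidates,
    tf_ids = tf_ids,
    stats = tibble(
      genome_size_bp = sum(Biostrings::width(contigs)),
      gc_genome_pct = 100 * book$gc_bases / book$atcg_bases,
      gene_count = cfg$n_genes,
      mean_gene_length_bp = mean(book$gene_spans),
      mean_introns_per_gene = mean(book$introns_per_gene),
      mean_intron_size_bp = if (length(book$intron_sizes))
        mean(book$intron_sizes) else NA_real_,
      mean_exon_size_bp = mean(book$exon_sizes)),
    variant_plan_counts = table(truth_variants$category)
  )
  structure(list(annotation = annotation, variants = variants,
                 counts = counts, samples = samples, lengths = lengths,
                 secretome = secretome, tf_ids = tf_ids, truth = truth,
                 config = cfg),
            class = "screen_scenario")
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat("<screen_scenario> seed ", x$config$seed, ": ",
      length(x$annotation$contigs), " contigs, ",
      nrow(x$annotation$genes), " genes, ", nrow(x$variants), " variants, ",
      nrow(x$samples), " samples, ", nrow(x$secretome), " proteins\n",
      sep = "")
  invisible(x)
}

#' Write a scenario bundle to disk
#'
#' Emits the standard-format fixture files: `genome.fasta`, `genes.gff3`,
#' `variants.vcf`, `counts.tsv`, `samples.tsv`, `gene_lengths.tsv`,
#' `secretome.tsv`, `tf_genes.txt`, `truth.json` and `scenario.yaml`.
#' Byte-identical for the same scenario.
#'
#' @param scenario A `screen_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_genome_fasta(scenario$annotation$contigs, fp("genome.fasta"))
  write_gene_models(scenario$annotation, fp("genes.gff3"))
  write_variants_vcf(scenario$variants, scenario$annotation$contigs,
                     fp("variants.vcf"))
  readr::write_tsv(scenario$counts, fp("counts.tsv"))
  readr::write_tsv(scenario$samples, fp("samples.tsv"))
  readr::write_tsv(scenario$lengths, fp("gene_lengths.tsv"))
  readr::write_tsv(scenario$secretome, fp("secretome.tsv"))
  writeLines(scenario$tf_ids, fp("tf_genes.txt"))
  truth <- scenario$truth
  truth$variant_plan_counts <- as.list(truth$variant_plan_counts)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  cfg <- scenario$config
  cfg$variant_plan <- as.list(cfg$variant_plan)
  yaml::write_yaml(unclass(cfg), fp("scenario.yaml"))
  invisible(dir)
}

#' Read a scenario bundle from disk
#'
#' Round-trips the files written by [write_scenario()] through the
#' package's standard readers.
#'
#' @param dir Directory written by [write_scenario()].
#' @return A list with elements `annotation`, `variants`, `counts`,
#'   `samples`, `lengths`, `secretome`, `tf_ids`.
#' @export
read_scenario <- function(dir) {
  contigs <- read_genome_fasta(file.path(dir, "genome.fasta"))
  annotation <- read_gene_models(file.path(dir, "genes.gff3"), contigs)
  list(
    annotation = annotation,
    variants = read_variants(file.path(dir, "variants.vcf"), annotation),
    counts = read_counts(file.path(dir, "counts.tsv")),
    samples = read_sample_map(file.path(dir, "samples.tsv")),
    lengths = read_gene_lengths(file.path(dir, "gene_lengths.tsv")),
    secretome = read_secretome(file.path(dir, "secretome.tsv")),
    tf_ids = read_tf_list(file.path(dir, "tf_genes.txt"))
  )
}
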
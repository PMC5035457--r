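# Hand-built two-contig toy genome used across test files.
#
# c1 layout (1-based):
#   1..100    filler ("ACGT" x 25)
#   101..109  gplus exon 1  "ATGAAATGC"           (M K C)
#   110..119  gplus intron  "GTTTTTTTAG"
#   120..128  gplus exon 2  "TACGGATGA"           (Y G *)
#   129..200  filler "T" x 72
#   201..218  gminus (single exon, strand -), genomic slice
#             "CTAAAATCGTTCAGGCAT" = revcomp("ATGCCTGAACGATTTTAG")
#             protein M P E R F *
#   219..400  filler "C" x 182
# c2 layout:
#   1..2000   filler ("ACGT" x 500)
#   2001..2018 gfar (strand +, single exon) "ATGAAAGGCTTTTGCTAA"
#              protein M K G F C *
#   2019..2400 filler "G" x 382
toy_annotation <- function() {
  c1 <- paste0(strrep("ACGT", 25),
               "ATGAAATGC", "GTTTTTTTAG", "TACGGATGA",
               strrep("T", 72),
               "CTAAAATCGTTCAGGCAT",
               strrep("C", 182))
  c2 <- paste0(strrep("ACGT", 500), "ATGAAAGGCTTTTGCTAA", strrep("G", 382))
  contigs <- Biostrings::DNAStringSet(c(c1 = c1, c2 = c2))
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus", "gfar"),
    contig_id = c("c1", "c1", "c2"),
    strand = c("+", "-", "+"),
    start = c(101L, 201L, 2001L),
    end = c(128L, 218L, 2018L))
  cds <- tibble::tibble(
    gene_id = c("gplus", "gplus", "gminus", "gfar"),
    start = c(101L, 120L, 201L, 2001L),
    end = c(109L, 128L, 218L, 2018L))
  genome_annotation(contigs, genes, cds)
}

# one-row variant tibble in the package's internal shape
make_variant <- function(contig, pos, ref, alt) {
  tibble::tibble(
    variant_id = paste0(contig, ":", pos, ":", ref, ">", alt),
    contig_id = contig, pos = as.integer(pos), ref = ref, alt = alt,
    vclass = regscreen:::variant_class(ref, alt))
}

# default scenario, generated once per test session
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- generate_scenario(scenario_config(seed = seed))
  }
  .scenario_cache[[key]]
}

# simulate the DE power fixture: 200 null genes plus 20 planted effects
# (half up, half down) at the given |log2FC|, NB(mu = depth, alpha), r vs r
make_power_counts <- function(seed, n_null = 200L, n_de = 20L, lfc = 3,
                              depth = 500, dispersion = 0.1, reps = 3L) {
  withr::with_seed(seed, {
    ng <- n_null + n_de
    true_lfc <- c(rep(0, n_null), rep(c(lfc, -lfc), each = n_de / 2))
    mu <- rep(depth, ng)
    sample_ids <- c(paste0("a", seq_len(reps)), paste0("b", seq_len(reps)))
    m <- vapply(seq_len(2L * reps), function(j) {
      mu_j <- if (j > reps) mu * 2^true_lfc else mu
      rnbinom(ng, size = 1 / dispersion, mu = mu_j)
    }, numeric(ng))
    colnames(m) <- sample_ids
    list(
      counts = dplyr::bind_cols(
        tibble::tibble(gene_id = sprintf("g%04d", seq_len(ng))),
        tibble::as_tibble(m)),
      samples = tibble::tibble(sample_id = sample_ids,
                               strain = rep(c("S1", "S2"), each = reps)),
      lengths = tibble::tibble(gene_id = sprintf("g%04d", seq_len(ng)),
                               length_bp = 1000L),
      true_lfc = true_lfc)
  })
}
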
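test_that("FASTA reading normalizes case and enforces the DNA alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "acGT", ">c2", "NNAC"), f)
  contigs <- read_genome_fasta(f)
  expect_equal(names(contigs), c("c1", "c2"))
  expect_equal(as.character(contigs[["c1"]]), "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_genome_fasta(f), "duplicate")

  writeLines(c(">a", "ACGU"), f)
  expect_error(read_genome_fasta(f), "non-IUPAC")

  writeLines(character(0), f)
  expect_error(read_genome_fasta(f))
})

test_that("GFF3 round trip preserves gene models and flags bad input", {
  ann <- toy_annotation()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(ann, gff)
  back <- read_gene_models(gff, ann$contigs)
  expect_setequal(back$genes$gene_id, ann$genes$gene_id)
  expect_equal(
    dplyr::arrange(back$cds, gene_id, start),
    dplyr::arrange(ann$cds, gene_id, start))
  # intron structure parsed: gplus has two segments
  expect_equal(sum(back$cds$gene_id == "gplus"), 2L)

  # CDS beyond contig bounds is a hard error
  bad <- c("##gff-version 3",
           "c1\tx\tgene\t1\t500\t.\t+\t.\tID=g1",
           "c1\tx\tmRNA\t1\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
           "c1\tx\tCDS\t1\t500\t.\t+\t0\tID=g1.c;Parent=g1.t1")
  writeLines(bad, gff)
  expect_error(read_gene_models(gff, ann$contigs), "bounds")

  # unresolvable CDS parent
  orphan <- c("##gff-version 3",
              "c1\tx\tgene\t101\t128\t.\t+\t.\tID=g1",
              "c1\tx\tCDS\t101\t109\t.\t+\t0\tID=z;Parent=nope")
  writeLines(orphan, gff)
  expect_error(read_gene_models(gff, ann$contigs), "parent")
})

test_that("first mRNA isoform is retained with a warning", {
  ann <- toy_annotation()
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t101\t128\t.\t+\t.\tID=g1",
    "c1\tx\tmRNA\t101\t128\t.\t+\t.\tID=g1.t1;Parent=g1",
    "c1\tx\tmRNA\t101\t128\t.\t+\t.\tID=g1.t2;Parent=g1",
    "c1\tx\tCDS\t101\t109\t.\t+\t0\tID=a;Parent=g1.t1",
    "c1\tx\tCDS\t120\t128\t.\t+\t0\tID=a;Parent=g1.t1",
    "c1\tx\tCDS\t101\t128\t.\t+\t0\tID=b;Parent=g1.t2"), gff)
  expect_warning(back <- read_gene_models(gff, ann$contigs), "isoform")
  segs <- back$cds[back$cds$gene_id == "g1", ]
  expect_equal(segs$start, c(101L, 120L))
  expect_equal(segs$end, c(109L, 128L))
})

test_that("spliced CDS honours transcript order and strand", {
  ann <- toy_annotation()
  expect_equal(spliced_cds(ann, "gplus"), "ATGAAATGCTACGGATGA")
  expect_equal(spliced_cds(ann, "gminus"), "ATGCCTGAACGATTTTAG")
  expect_error(spliced_cds(ann, "nope"), "unknown gene_id")

  # three-exon minus-strand gene equals the hand-spliced string
  tx <- "ATGCATGAACCCGGGTTTTAA"  # M H E P G F *
  e1 <- substr(tx, 1, 6); i1 <- "GTAAAG"
  e2 <- substr(tx, 7, 15); i2 <- "GTCCAG"
  e3 <- substr(tx, 16, 21)
  fwd <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(e1, i1, e2, i2, e3))))
  contigs <- Biostrings::DNAStringSet(c(cx = paste0("TTTT", fwd, "TTTT")))
  # transcript-relative exon intervals flipped onto the forward strand
  L <- nchar(fwd)
  rel <- data.frame(start = c(1, 7 + 6, 16 + 12), end = c(6, 15 + 6, 21 + 12))
  cds <- tibble::tibble(gene_id = "m3",
                        start = 4 + (L - rel$end + 1),
                        end = 4 + (L - rel$start + 1))
  ann3 <- genome_annotation(
    contigs,
    tibble::tibble(gene_id = "m3", contig_id = "cx", strand = "-",
                   start = min(cds$start), end = max(cds$end)),
    cds)
  expect_equal(spliced_cds(ann3, "m3"), tx)
  expect_equal(translate_cds(spliced_cds(ann3, "m3")), "MHEPGF*")
})

test_that("minus-strand splicing is the reverse complement of plus reading", {
  ann <- cached_scenario()$annotation
  minus <- ann$genes$gene_id[ann$genes$strand == "-"]
  for (g in head(minus, 5)) {
    segs <- ann$cds[ann$cds$gene_id == g, ]
    fwd <- paste(vapply(seq_len(nrow(segs)), function(i) {
      as.character(Biostrings::subseq(ann$contigs[[segs$contig_id[i]]],
                                      segs$start[i], segs$end[i]))
    }, character(1)), collapse = "")
    expect_equal(
      spliced_cds(ann, g),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
  }
})

test_that("translation follows the standard code with stop and N semantics", {
  expect_equal(translate_cds("ATGTGA"), "M*")
  expect_equal(translate_cds("ATGAAATAAAAA"), "MK*")
  expect_equal(substr(translate_cds("ATGANACCC"), 2, 2), "X")
  expect_equal(translate_cds("ATGAAA"), "MK")   # no stop: runs to the end
  expect_equal(translate_cds("ATGAAAT"), "MK")  # trailing partial codon ignored
  expect_error(translate_cds("AT"))
})

test_that("genome statistics match hand counts and handle no genes", {
  empty <- Biostrings::DNAStringSet(c(c1 = "ATGC"))
  ann0 <- structure(list(contigs = empty,
                         genes = tibble::tibble(gene_id = character(),
                                                contig_id = character(),
                                                strand = character(),
                                                start = integer(),
                                                end = integer()),
                         cds = tibble::tibble(gene_id = character(),
                                              contig_id = character(),
                                              strand = character(),
                                              start = integer(),
                                              end = integer())),
                    class = "genome_annotation")
  s0 <- genome_stats(ann0)
  expect_equal(s0$genome_size_bp, 4)
  expect_equal(s0$gc_genome_pct, 50)
  expect_true(is.na(s0$mean_gene_length_bp))

  ann <- toy_annotation()
  s <- genome_stats(ann)
  expect_equal(s$gene_count, 3L)
  # gplus: segments 101..109 and 120..128 -> one intron of 10 bp
  expect_equal(s$mean_introns_per_gene, 1 / 3)
  expect_equal(s$mean_intron_size_bp, 10)
  expect_equal(s$mean_exon_size_bp, mean(c(9, 9, 18, 18)))
  expect_equal(s$mean_gene_length_bp, mean(c(28, 18, 18)))

  # invariant under permutation of contig and gene order
  perm <- genome_annotation(
    rev(ann$contigs),
    ann$genes[c(3, 1, 2), ],
    ann$cds[sample.int(nrow(ann$cds)), c("gene_id", "start", "end")])
  expect_equal(genome_stats(perm), s)
})

test_that("interval index agrees with a brute-force linear scan", {
  ann <- cached_scenario()$annotation
  withr::with_seed(11, {
    for (i in seq_len(300)) {
      contig <- sample(names(ann$contigs), 1)
      pos <- sample(Biostrings::width(ann$contigs[contig]), 1)
      idx <- features_at(ann, contig, pos)
      genes_ls <- ann$genes$gene_id[ann$genes$contig_id == contig &
                                      ann$genes$start <= pos &
                                      ann$genes$end >= pos]
      cds_ls <- ann$cds$gene_id[ann$cds$contig_id == contig &
                                  ann$cds$start <= pos & ann$cds$end >= pos]
      expect_setequal(idx$gene_id[idx$feature == "gene"], genes_ls)
      expect_setequal(idx$gene_id[idx$feature == "cds"], cds_ls)
    }
  })
})

test_that("CDS/genome coordinate maps are mutually inverse on both strands", {
  ann <- toy_annotation()
  for (g in c("gplus", "gminus", "gfar")) {
    L <- nchar(spliced_cds(ann, g))
    cpos <- seq_len(L)
    gpos <- regscreen:::cds_to_genome(ann, g, cpos)
    expect_equal(regscreen:::genome_to_cds(ann, g, gpos), cpos)
  }
  # first CDS base of the minus-strand gene is its highest coordinate
  expect_equal(regscreen:::cds_to_genome(ann, "gminus", 1L), 218L)
})
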
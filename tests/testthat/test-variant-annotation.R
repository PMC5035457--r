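test_that("VCF reading splits multi-allelics and validates REF", {
  ann <- toy_annotation()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t5\t.\tA\tG\t.\tPASS\t.",
    "c1\t9\t.\tA\tG,T\t.\tPASS\t."), vcf)
  v <- read_variants(vcf, ann)
  expect_equal(nrow(v), 3L)
  expect_equal(v$vclass, rep("SNV", 3))
  expect_equal(v$alt, c("G", "G", "T"))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t5\t.\tT\tG\t.\tPASS\t."), vcf)  # genome base at c1:5 is A
  expect_error(read_variants(vcf, ann), "REF mismatch.*c1:5")
})

test_that("variant classes derive from ref/alt lengths with the anchor rule", {
  expect_equal(regscreen:::variant_class("A", "G"), "SNV")
  expect_equal(regscreen:::variant_class("AT", "A"), "deletion")
  expect_equal(regscreen:::variant_class("A", "AT"), "insertion")
  expect_equal(regscreen:::variant_class("AT", "GC"), "other")
})

test_that("region classification partitions CDS > intron > intergenic", {
  ann <- toy_annotation()
  v <- dplyr::bind_rows(
    make_variant("c1", 105, "A", "G"),    # inside gplus exon 1
    make_variant("c1", 114, "T", "A"),    # inside gplus intron
    make_variant("c1", 50, "T", "A"),     # intergenic
    make_variant("c1", 108, "GCGTTTTTTT", "G"))  # deletion across the junction
  out <- classify_region(v, ann)
  expect_equal(out$region, c("CDS", "intron", "intergenic", "CDS"))
})

test_that("SNV consequences are called per codon on both strands", {
  ann <- toy_annotation()
  # gplus codon 2 AAA -> AAG: synonymous (third position)
  syn <- coding_consequence(make_variant("c1", 106, "A", "G"), ann)
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$aa_change, "K2K")
  # gplus codon 3 TGC -> TGA: stop gain
  sg <- coding_consequence(make_variant("c1", 109, "C", "A"), ann)
  expect_equal(sg$consequence, "stop_gain")
  expect_equal(sg$aa_change, "C3*")
  # gminus codon 2 CCT -> CAT (P2H): cds pos 5 maps to genome 214;
  # the alt on the genome is the complement of the transcript base
  mis <- coding_consequence(make_variant("c1", 214, "G", "T"), ann)
  expect_equal(mis$gene_id, "gminus")
  expect_equal(mis$consequence, "missense")
  expect_equal(mis$aa_change, "P2H")
  # gplus stop codon TGA -> CGA read through: stop loss
  sl <- coding_consequence(make_variant("c1", 126, "T", "C"), ann)
  expect_equal(sl$consequence, "stop_loss")
  # start codon destroyed
  st <- coding_consequence(make_variant("c1", 101, "A", "C"), ann)
  expect_equal(st$consequence, "start_loss")
})

test_that("indel consequences follow the mod-3 and boundary conventions", {
  ann <- toy_annotation()
  # 1-bp deletion inside gplus exon 1
  fs <- coding_consequence(make_variant("c1", 104, "AA", "A"), ann)
  expect_equal(fs$consequence, "frameshift")
  # 3-bp deletion fully inside the exon: in-frame
  inf <- coding_consequence(make_variant("c1", 103, "GAAA", "G"), ann)
  expect_equal(inf$consequence, "inframe_indel")
  # 3-bp deletion spanning the exon/intron boundary: frameshift by convention
  sp <- coding_consequence(make_variant("c1", 107, "TGCG", "T"), ann)
  expect_equal(sp$consequence, "frameshift")
  # 1-bp insertion inside the exon
  ins <- coding_consequence(make_variant("c1", 104, "A", "AT"), ann)
  expect_equal(ins$consequence, "frameshift")
})

test_that("analytic calls equal the mutate-and-retranslate oracle", {
  sc <- cached_scenario()
  ann <- sc$annotation
  planted <- sc$truth$variants
  coding <- planted[planted$region == "CDS", ]
  calls <- coding_consequence(sc$variants, ann)
  for (i in seq_len(nrow(coding))) {
    v <- sc$variants[sc$variants$variant_id == coding$variant_id[i], ]
    expected <- oracle_consequence(ann, v, coding$gene_id[i])
    got <- calls$consequence[calls$variant_id == coding$variant_id[i] &
                               calls$gene_id == coding$gene_id[i]]
    expect_equal(got, expected, info = coding$variant_id[i])
  }
})

test_that("consequence calls are invariant under genome reverse complement", {
  ann <- toy_annotation()
  # rebuild the fixture with every contig reverse-complemented and all
  # coordinates/strands remapped
  widths <- stats::setNames(Biostrings::width(ann$contigs),
                            names(ann$contigs))
  rc_contigs <- Biostrings::reverseComplement(ann$contigs)
  names(rc_contigs) <- names(ann$contigs)
  flip <- function(df) {
    w <- widths[df$contig_id]
    tibble::tibble(df,
                   new_start = w - df$end + 1L,
                   new_end = w - df$start + 1L)
  }
  g2 <- flip(ann$genes)
  genes_rc <- tibble::tibble(gene_id = g2$gene_id, contig_id = g2$contig_id,
                             strand = ifelse(g2$strand == "+", "-", "+"),
                             start = g2$new_start, end = g2$new_end)
  c2 <- flip(ann$cds)
  cds_rc <- tibble::tibble(gene_id = c2$gene_id, start = c2$new_start,
                           end = c2$new_end)
  ann_rc <- genome_annotation(rc_contigs, genes_rc, cds_rc)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cases <- list(c("c1", 106, "A", "G"), c("c1", 109, "C", "A"),
                c("c1", 214, "G", "T"))
  for (cs in cases) {
    v <- make_variant(cs[1], as.integer(cs[2]), cs[3], cs[4])
    pos_rc <- widths[cs[1]] - as.integer(cs[2]) + 1L
    v_rc <- make_variant(cs[1], pos_rc, rc(cs[3]), rc(cs[4]))
    expect_equal(coding_consequence(v_rc, ann_rc)$consequence,
                 coding_consequence(v, ann)$consequence)
  }
})

test_that("promoter/terminator windows are strict, bounded and strand-aware", {
  ann <- toy_annotation()
  w <- window_config()
  # 51 bp upstream of gplus ATG
  f1 <- regulatory_flags(make_variant("c1", 50, "C", "A"), ann, w)
  expect_true(any(f1$gene_id == "gplus" & f1$flag == "promoter"))
  # between two convergent stops: terminator of both genes
  f2 <- regulatory_flags(make_variant("c1", 150, "T", "A"), ann, w)
  expect_setequal(f2$gene_id[f2$flag == "terminator"], c("gplus", "gminus"))
  # boundary: gfar tss at c2:2001; 1500 bp away flagged, 1501 not
  at1500 <- regulatory_flags(make_variant("c2", 501, "A", "G"), ann, w)
  expect_true(any(at1500$gene_id == "gfar" & at1500$flag == "promoter"))
  at1501 <- regulatory_flags(make_variant("c2", 500, "T", "G"), ann, w)
  expect_false(any(at1501$gene_id == "gfar" & at1501$flag == "promoter"))
  # upstream on the minus strand means higher coordinates
  f3 <- regulatory_flags(make_variant("c1", 230, "C", "A"), ann, w)
  expect_true(any(f3$gene_id == "gminus" & f3$flag == "promoter"))
  # CDS variants carry no window flags by default, but can be included
  cdsv <- make_variant("c1", 105, "A", "G")
  expect_equal(nrow(regulatory_flags(cdsv, ann, w)), 0L)
})

test_that("enlarging the promoter window never removes a flag", {
  sc <- cached_scenario()
  small <- regulatory_flags(sc$variants, sc$annotation, window_config(800, 100))
  big <- regulatory_flags(sc$variants, sc$annotation, window_config(1500, 200))
  key <- function(f) paste(f$variant_id, f$gene_id, f$flag)
  expect_true(all(key(small) %in% key(big)))
})

test_that("variant summaries partition SNVs and count planted categories", {
  empty <- annotate_variants(
    tibble::tibble(variant_id = character(), contig_id = character(),
                   pos = integer(), ref = character(), alt = character(),
                   vclass = character()),
    toy_annotation())
  s0 <- summarize_variants(empty)
  expect_true(all(unlist(s0) == 0))

  sc <- cached_scenario()
  annotated <- annotate_variants(sc$variants, sc$annotation)
  s <- summarize_variants(annotated)
  plan <- sc$config$variant_plan
  expect_equal(s$snv_total, s$snv_cds + s$snv_intergenic + s$snv_intron)
  expect_equal(s$snv_cds,
               unname(plan["synonymous"] + plan["missense"] +
                        plan["stop_gain"]))
  expect_equal(s$snv_intron, unname(plan["intron"]))
  expect_equal(s$snv_intergenic,
               unname(plan["intergenic"] + plan["promoter"] +
                        plan["terminator"]))
  expect_equal(s$promoter_snvs, unname(plan["promoter"]))
  expect_equal(s$terminator_snvs, unname(plan["terminator"]))
  expect_equal(s$deletions, unname(plan["frameshift_deletion"]))
  expect_equal(s$insertions, unname(plan["insertion"]))
  expect_equal(s$indels_in_cds, unname(plan["frameshift_deletion"]))
})
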
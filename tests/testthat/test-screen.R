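# minimal annotated-variant rows for rule tests
annot_row <- function(gene, consequence = "none", promoter = FALSE,
                      terminator = FALSE) {
  tibble::tibble(
    variant_id = paste0("v_", gene, "_", consequence,
                        substr(paste0(promoter, terminator), 1, 2)),
    contig_id = "c", pos = 1L, ref = "A", alt = "G", vclass = "SNV",
    region = if (consequence == "none") "intergenic" else "CDS",
    gene_id = gene, consequence = consequence, aa_change = "",
    promoter = promoter, terminator = terminator)
}

de_row <- function(gene, M, probability = 0) {
  tibble::tibble(gene_id = gene, M = M, D = abs(M),
                 probability = probability,
                 is_de = abs(M) >= 1 & probability >= 0.8)
}

test_that("rule A needs a qualifying variant and a twofold change", {
  cfg <- screen_config()
  ann <- dplyr::bind_rows(
    annot_row("gProm", promoter = TRUE),
    annot_row("gSyn", consequence = "synonymous"),
    annot_row("gMis", consequence = "missense"),
    annot_row("gTerm", terminator = TRUE))
  de <- dplyr::bind_rows(
    de_row("gProm", 2.1), de_row("gSyn", 3), de_row("gMis", 0.4),
    de_row("gTerm", -1.0))
  expect_equal(rule_a(ann, de, cfg), c("gProm", "gTerm"))
})

test_that("rule B selects only transcription factors with damaging CDS hits", {
  cfg <- screen_config(tf_gene_ids = c("tf1", "tf2", "tf3"))
  ann <- dplyr::bind_rows(
    annot_row("tf1", consequence = "missense"),     # S725N-style case
    annot_row("tf2", consequence = "synonymous"),
    annot_row("tf3", promoter = TRUE),
    annot_row("notf", consequence = "missense"))
  expect_equal(rule_b(ann, cfg), "tf1")
})

test_that("rule C selects DE transcription factors without CDS variants", {
  cfg <- screen_config(tf_gene_ids = c("tf1", "tf2", "tf3"))
  ann <- annot_row("tf3", consequence = "missense")
  de <- dplyr::bind_rows(
    de_row("tf1", -1.82, 0.95),  # down-regulated TF, high probability
    de_row("tf2", -0.5, 0.99),   # below the fold threshold
    de_row("tf3", 2.5, 0.99))    # DE but already a rule-B gene
  expect_equal(rule_c(de, ann, cfg), "tf1")
})

test_that("screen output is exactly the union of the rules with provenance", {
  sc <- cached_scenario()
  annotated <- annotate_variants(sc$variants, sc$annotation)
  de <- de_call(sc$counts, sc$samples, sc$lengths,
                de_config(seed = sc$config$seed))
  cfg <- screen_config(tf_gene_ids = sc$tf_ids)
  cands <- screen_candidates(annotated, de, cfg)
  a <- rule_a(annotated, de, cfg)
  b <- rule_b(annotated, cfg)
  cc <- rule_c(de, annotated, cfg)
  expect_equal(cands$gene_id, sort(unique(c(a, b, cc))))
  expect_equal(cands$gene_id[cands$rule_a], a)
  expect_equal(cands$gene_id[cands$rule_b], b)
  expect_equal(cands$gene_id[cands$rule_c], cc)
  expect_true(all(nchar(cands$rules) > 0))
  gl <- glance(cands)
  expect_equal(unlist(gl),
               c(rule_a = length(a), rule_b = length(b), rule_c = length(cc),
                 total = nrow(cands)))
  expect_s3_class(autoplot(cands), "ggplot")
})

test_that("a gene can satisfy several rules and keeps all tags", {
  cfg <- screen_config(tf_gene_ids = "tfA")
  ann <- annot_row("tfA", promoter = TRUE)
  de <- de_row("tfA", -2, 0.95)
  cands <- screen_candidates(ann, de, cfg)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$rules, "A,C")
})

test_that("relaxing thresholds never removes a candidate", {
  sc <- cached_scenario()
  de <- de_call(sc$counts, sc$samples, sc$lengths,
                de_config(seed = sc$config$seed))
  strict_ann <- annotate_variants(sc$variants, sc$annotation,
                                  window_config(1000, 100))
  relaxed_ann <- annotate_variants(sc$variants, sc$annotation,
                                   window_config(2000, 400))
  strict <- screen_candidates(strict_ann, de,
                              screen_config(tf_gene_ids = sc$tf_ids,
                                            lfc_a = 1.5, lfc_c = 1.5,
                                            prob_c = 0.9))
  relaxed <- screen_candidates(relaxed_ann, de,
                               screen_config(tf_gene_ids = sc$tf_ids,
                                             lfc_a = 0.5, lfc_c = 0.5,
                                             prob_c = 0.5))
  expect_true(all(strict$gene_id %in% relaxed$gene_id))
})

test_that("empty inputs produce an empty candidate list with zero counts", {
  cfg <- screen_config()
  ann <- annot_row("g1")[0, ]
  de <- de_row("g1", 0)[0, ]
  cands <- screen_candidates(ann, de, cfg)
  expect_equal(nrow(cands), 0L)
  expect_equal(glance(cands)$total, 0L)
})

test_that("candidates outside the annotation namespace warn but are kept", {
  cfg <- screen_config(tf_gene_ids = "ghost")
  ann <- annot_row("ghost", consequence = "missense")
  de <- de_row("ghost", 0)
  expect_warning(
    cands <- screen_candidates(ann, de, cfg,
                               annotation = toy_annotation()),
    "unknown to the genome annotation")
  expect_equal(cands$gene_id, "ghost")
})
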
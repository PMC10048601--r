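test_that("keyword selection is case-insensitive substring matching", {
  g <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    description = c("Heat shock protein 70 kDa",
                    "Pollen receptor-like kinase 3",
                    "Ubiquitin ligase",
                    "Flowering locus T, heat induced"),
    stringsAsFactors = FALSE)
  sel <- keyword_select(g)
  expect_equal(sel$heat$gene_id, c("a", "d"))
  expect_equal(sel$heat$subcategory[1], "HSP")
  expect_equal(sel$reproduction$gene_id, c("b", "d"))
  expect_equal(sel$reproduction$subcategory,
               c("pollen", "flower"))
  expect_equal(sel$both, "d")  # a gene may join both lists
  # HSF vocabulary routes to the HSF subcategory
  g2 <- data.frame(gene_id = "e",
                   description = "Heat stress transcription factor A-5")
  expect_equal(keyword_select(g2)$heat$subcategory, "HSF")
  expect_error(keyword_config(heat_keywords = character()), "non-empty")
})

test_that("gene/interval overlap uses 1-based inclusive semantics", {
  genes <- data.frame(gene_id = "g", chrom = "chr1",
                      tx_start = 100, tx_end = 200)
  q <- function(s, e) data.frame(qtl_id = "q", chrom = "chr1",
                                 start = s, end = e)
  expect_equal(nrow(colocalize(genes, q(150, 500))), 1L)
  expect_equal(nrow(colocalize(genes, q(201, 500))), 0L)  # touching-disjoint
  expect_equal(nrow(colocalize(genes, q(200, 500))), 1L)  # one shared base
  expect_error(colocalize(genes, data.frame(qtl_id = "q", chrom = "chr9",
                                            start = 1, end = 10)),
               class = "introcand_namespace_error")
})

mk_prio_inputs <- function() {
  genes <- gene_models(
    data.frame(gene_id = c("hsp1", "hsp2", "flo1", "neu1"),
               chrom = "chr1", strand = "+",
               tx_start = c(100, 5000, 9000, 13000),
               tx_end = c(1000, 6000, 10000, 14000),
               description = c("Heat shock protein", "Heat shock protein",
                               "Flowering locus T", "Ubiquitin ligase")),
    data.frame(gene_id = c("hsp1", "hsp2", "flo1", "neu1"),
               type = "exon", start = c(100, 5000, 9000, 13000),
               end = c(1000, 6000, 10000, 14000)))
  ann <- data.frame(chrom = "chr1", pos = c(150, 5100, 9100, 13100, 160),
                    ref = "A", alt = "T", vclass = "SNP",
                    gene = c("hsp1", "hsp2", "flo1", "neu1", "hsp1"),
                    region = "exon",
                    effect = c("missense_variant", "synonymous_variant",
                               "stop_gained", "missense_variant",
                               "frameshift_variant"),
                    impact = c("MODERATE", "LOW", "HIGH", "MODERATE",
                               "HIGH"),
                    stringsAsFactors = FALSE)
  regions <- data.frame(label = "p1_1", chrom = "chr1",
                        start = 1, end = 2000)
  qtls <- data.frame(qtl_id = c("FLN1", "FRN1"),
                     trait_class = c("Flower number", "Fruit number"),
                     chrom = "chr1", start = c(8500, 12500),
                     end = c(10500, 14500), stringsAsFactors = FALSE)
  list(genes = genes, ann = ann, regions = regions, qtls = qtls)
}

test_that("prioritization needs list membership, impact, and location", {
  x <- mk_prio_inputs()
  sel <- keyword_select(x$genes)
  cand <- prioritize(sel, x$ann, x$genes, x$regions, x$qtls)
  # hsp1: in region with HIGH+MODERATE -> in, with tallies
  # hsp2: only LOW -> out; flo1: flower QTL route, no region -> in
  # neu1: HIGH-equivalent impact but not in any list -> out
  expect_setequal(cand$gene_id, c("hsp1", "flo1"))
  h <- cand[cand$gene_id == "hsp1", ]
  expect_equal(h$high_n, 1L)
  expect_equal(h$moderate_n, 1L)
  expect_equal(h$region_label, "p1_1")
  f <- cand[cand$gene_id == "flo1", ]
  expect_true(is.na(f$region_label))
  expect_equal(f$qtl_ids, "FLN1")
  # every selected gene is reachable by region or flower-QTL route
  expect_true(all(!is.na(cand$region_label) | !is.na(cand$qtl_ids)))
  # strict flower classes drop nothing here (FLN1 is flower number)
  cand2 <- prioritize(sel, x$ann, x$genes, x$regions, x$qtls,
                      flower_classes = flower_trait_classes(strict = TRUE))
  expect_setequal(cand2$gene_id, cand$gene_id)
})

test_that("selection is monotone in QTLs and keywords", {
  x <- mk_prio_inputs()
  sel <- keyword_select(x$genes)
  base <- prioritize(sel, x$ann, x$genes, x$regions, x$qtls)
  # adding a QTL interval never shrinks the selection
  more <- rbind(x$qtls, data.frame(qtl_id = "FLN2",
                                   trait_class = "Flower number",
                                   chrom = "chr1", start = 4500, end = 6500))
  grown <- prioritize(sel, x$ann, x$genes, x$regions, more)
  expect_true(all(base$gene_id %in% grown$gene_id))
  # removing a keyword never grows it
  sel2 <- keyword_select(x$genes,
                         keyword_config(heat_keywords = "zzz-nomatch"))
  shrunk <- prioritize(sel2, x$ann, x$genes, x$regions, x$qtls)
  expect_true(all(shrunk$gene_id %in% base$gene_id))
  expect_false("hsp1" %in% shrunk$gene_id)
})

test_that("candidate summaries are permutation-invariant", {
  x <- mk_prio_inputs()
  cand <- prioritize(keyword_select(x$genes), x$ann, x$genes,
                     x$regions, x$qtls)
  s1 <- summarize_candidates(cand)
  s2 <- summarize_candidates(cand[rev(seq_len(nrow(cand))), ])
  expect_identical(s1, s2)
  s0 <- summarize_candidates(empty <- cand[0, ])
  expect_equal(s0$total, 0L)
  expect_equal(s0$high_impact_genes, 0L)
})

test_that("packaged fixtures load with the documented shape", {
  cand <- load_candidate_table()
  expect_equal(nrow(cand), 35L)
  expect_true(all(!is.na(cand$list)))
  expect_true(all(cand$high_n + cand$moderate_n >= 1))
  qtl <- load_qtl_trait_counts()
  expect_equal(nrow(qtl), 11L)
  expect_true(all(c("trait", "qtl_n") %in% names(qtl)))
})
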
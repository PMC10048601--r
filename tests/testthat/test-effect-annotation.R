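# The hand-built locus (see helper-sim.R): CDS codons are
# ATG GCT TGC | TTC AAG TAA split across two exons by one intron.

ann1 <- function(loc, v, ...) {
  annotate_effect(v[1, ], loc$gm, "g1", loc$seq, ...)
}

test_that("coding SNPs classify against the standard code (+ strand)", {
  loc <- tiny_locus("+")
  # codon 2 GCT(Ala) -> TCT(Ser): CDS position 4, genomic 40
  a <- ann1(loc, tiny_variant(40, "G", "T"))
  expect_equal(a$effect, "missense_variant")
  expect_equal(a$impact, "MODERATE")
  # codon 2 GCT -> GCC: synonymous (Ala)
  expect_equal(ann1(loc, tiny_variant(42, "T", "C"))$effect,
               "synonymous_variant")
  # codon 3 TGC(Cys) -> TGA: stop gained
  a2 <- ann1(loc, tiny_variant(45, "C", "A"))
  expect_equal(a2$effect, "stop_gained")
  expect_equal(a2$impact, "HIGH")
  # terminal TAA -> TAC(Tyr): stop lost
  expect_equal(ann1(loc, tiny_variant(66, "A", "C"))$effect, "stop_lost")
  # mismatching REF allele is a reference error
  expect_error(ann1(loc, tiny_variant(40, "C", "T")), "mismatch")
})

test_that("coding indels split by frame and codon alignment (+ strand)", {
  loc <- tiny_locus("+")
  s <- as.character(loc$seq)
  # delete codon 2 exactly (genomic 40-42, anchored at 39)
  del3 <- tiny_variant(39, substr(s, 39, 42), substr(s, 39, 39))
  expect_equal(ann1(loc, del3)$effect, "conservative_inframe_deletion")
  # same 3-bp deletion shifted by one base straddles codons
  del3b <- tiny_variant(40, substr(s, 40, 43), substr(s, 40, 40))
  expect_equal(ann1(loc, del3b)$effect, "disruptive_inframe_deletion")
  # 1-bp and 2-bp indels shift the frame
  del1 <- tiny_variant(40, substr(s, 40, 41), substr(s, 40, 40))
  expect_equal(ann1(loc, del1)$effect, "frameshift_variant")
  ins2 <- tiny_variant(40, substr(s, 40, 40),
                       paste0(substr(s, 40, 40), "AT"))
  a <- ann1(loc, ins2)
  expect_equal(a$effect, "frameshift_variant")
  expect_equal(a$impact, "HIGH")
  # 3-bp insertion between codons 1 and 2 (after CDS position 3) is
  # conservative; inside codon 2 it is disruptive
  ins_cons <- tiny_variant(39, substr(s, 39, 39),
                           paste0(substr(s, 39, 39), "GAA"))
  expect_equal(ann1(loc, ins_cons)$effect, "conservative_inframe_insertion")
  ins_disr <- tiny_variant(40, substr(s, 40, 40),
                           paste0(substr(s, 40, 40), "GAA"))
  expect_equal(ann1(loc, ins_disr)$effect, "disruptive_inframe_insertion")
})

test_that("noncoding contexts map to their region terms (+ strand)", {
  loc <- tiny_locus("+")
  expect_equal(ann1(loc, tiny_variant(33, "T", "G"))$effect,
               "five_prime_UTR_variant")
  expect_equal(ann1(loc, tiny_variant(69, "C", "G"))$effect,
               "three_prime_UTR_variant")
  # intron interior
  ib <- substr(as.character(loc$seq), 52, 52)
  a <- ann1(loc, tiny_variant(52, ib, setdiff(c("A", "C", "G", "T"), ib)[1]))
  expect_equal(a$effect, "intron_variant")
  expect_equal(a$impact, "MODIFIER")
  # first intron base = donor site (HIGH); last = acceptor
  expect_equal(ann1(loc, tiny_variant(46, "G", "C"))$effect,
               "splice_donor_variant")
  expect_equal(ann1(loc, tiny_variant(57, "G", "C"))$effect,
               "splice_acceptor_variant")
  # third intron base is splice region (LOW)
  a3 <- ann1(loc, tiny_variant(48, substr(as.character(loc$seq), 48, 48),
                               "C"))
  expect_equal(a3$effect, "splice_region_variant")
  expect_equal(a3$impact, "LOW")
})

test_that("flanks and intergenic placement are strand-aware", {
  loc <- tiny_locus("+")
  l <- locate_variant(tiny_variant(20, "A", "T")[1, ], loc$gm, flank_bp = 50)
  expect_equal(l$region, "upstream")
  l2 <- locate_variant(tiny_variant(110, "A", "T")[1, ], loc$gm,
                       flank_bp = 50)
  expect_equal(l2$region, "downstream")
  l3 <- locate_variant(tiny_variant(250, "A", "T")[1, ], loc$gm,
                       flank_bp = 50)
  expect_equal(l3$region, "intergenic")
  expect_true(is.na(l3$gene))
  # minus-strand gene flips the flank sidedness
  locm <- tiny_locus("-")
  lm <- locate_variant(tiny_variant(110, "A", "T")[1, ], locm$gm,
                       flank_bp = 50)
  expect_equal(lm$region, "upstream")
})

test_that("effects are identical on the reverse-complemented locus", {
  loc <- tiny_locus("-")
  s <- as.character(loc$seq)
  # CDS coordinates mirror: cds position c sits at genomic 66 - c + 1
  # for the first coding exon (CDS 1-9 at genomic 66..58)
  # codon 2 position 4 (transcript G>T) = genomic 63, complemented alleles
  a <- ann1(loc, tiny_variant(63, substr(s, 63, 63), "A"))
  expect_equal(a$effect, "missense_variant")
  # stop gained: transcript CDS position 9 C>A = genomic 58, G>T
  expect_equal(ann1(loc, tiny_variant(58, "G", "T"))$effect, "stop_gained")
  # splice donor is now the intron base adjacent to the right exon
  expect_equal(ann1(loc, tiny_variant(57,
                                      substr(s, 57, 57),
                                      setdiff(c("A", "C", "G", "T"),
                                              substr(s, 57, 57))[1]))$effect,
               "splice_donor_variant")
  # 5'UTR sits at high genomic coordinates
  expect_equal(ann1(loc, tiny_variant(69, substr(s, 69, 69),
                                      setdiff(c("A", "C", "G", "T"),
                                              c(substr(s, 69, 69),
                                                "T"))[1]))$effect,
               "five_prime_UTR_variant")
})

test_that("a deletion fusing CDS of opposite-strand genes is HIGH", {
  # two adjacent genes on opposite strands with CDS 20 bp apart
  g1 <- build_gene_for_test("+", 31L, "gA")
  g2 <- build_gene_for_test("-", 151L, "gB")
  gm <- gene_models(rbind(g1$gene, g2$gene),
                    rbind(g1$features, g2$features))
  seq <- Biostrings::DNAString(strrep("ACGT", 100))
  v <- variant_records("chr1", 40,
                       ref = as.character(Biostrings::subseq(seq, 40, 160)),
                       alt = as.character(Biostrings::subseq(seq, 40, 40)))
  ann <- annotate_variants(v, gm, Biostrings::DNAStringSet(
    stats::setNames(as.character(seq), "chr1")))
  expect_true(all(ann$effect == "bidirectional_gene_fusion"))
  expect_true(all(ann$impact == "HIGH"))
  expect_setequal(ann$gene, c("gA", "gB"))
})

test_that("impact summaries count the most severe call per variant", {
  expect_equal(summarize_impacts(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), vclass = character(), gene = character(),
               region = character(), effect = character(),
               impact = character()))$n_variants, 0L)
  ann <- data.frame(chrom = "chr1", pos = rep(1:1000, each = 1), ref = "A",
                    alt = "T", vclass = "SNP", gene = NA,
                    region = "intergenic", effect = "intergenic_variant",
                    impact = "MODIFIER", stringsAsFactors = FALSE)
  s <- summarize_impacts(ann)
  expect_equal(s$by_impact$percent[s$by_impact$impact == "MODIFIER"], 100)
  # one variant annotated in two genes counts once, at its worst impact
  ann2 <- rbind(ann[1:2, ],
                transform(ann[1, ], gene = "g", region = "exon",
                          effect = "missense_variant", impact = "MODERATE"))
  s2 <- summarize_impacts(ann2)
  expect_equal(s2$n_variants, 2L)
  expect_equal(s2$by_impact$n[s2$by_impact$impact == "MODERATE"], 1L)
  expect_equal(sum(s2$by_impact$n), 2L)
})

test_that("annotated VCF export carries the ANN tag per overlapping gene", {
  loc <- tiny_locus("+")
  v <- rbind(tiny_variant(40, "G", "T"), tiny_variant(250, "A", "T"))
  ann <- annotate_variants(v, loc$gm, loc$genome, flank_bp = 50)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_annotations_vcf(ann, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)
  expect_match(body[1], "ANN=g1\\|exon\\|missense_variant\\|MODERATE")
  expect_match(body[2], "ANN=\\|intergenic\\|intergenic_variant\\|MODIFIER")
  # the exported file still parses as VCF
  back <- read_variants(f)
  expect_equal(back$pos, c(40L, 250L))
})
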
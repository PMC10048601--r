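mk_genome <- function(seq) {
  Biostrings::DNAStringSet(stats::setNames(seq, "chr1"))
}

prom_gene <- function(strand, tx_start, tx_end) {
  gene_models(
    data.frame(gene_id = "g", chrom = "chr1", strand = strand,
               tx_start = tx_start, tx_end = tx_end, description = "x"),
    data.frame(gene_id = "g", type = c("exon", "cds"),
               start = tx_start, end = tx_end))
}

test_that("promoter extraction is strand-aware and edge-truncated", {
  set.seed(2)
  L <- 8000
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  genome <- mk_genome(seq)
  # + gene at tx_start 3001: promoter = bases 1..3000
  p <- extract_promoter(prom_gene("+", 3001L, 3600L), "g", genome)
  expect_equal(as.character(p), substr(seq, 1, 3000))
  # - gene ending at L-3000: promoter = revcomp of the 3000 bases after it
  gmm <- prom_gene("-", L - 3600L, L - 3000L)
  pm <- extract_promoter(gmm, "g", genome)
  expect_equal(as.character(pm),
               oracle_revcomp(substr(seq, L - 3000 + 1, L)))
  # near the chromosome start the promoter truncates with a warning
  expect_warning(pt <- extract_promoter(prom_gene("+", 100L, 400L), "g",
                                        genome),
                 "truncated")
  expect_equal(length(pt), 99L)
  expect_error(extract_promoter(prom_gene("+", 3001L, 3600L), "g",
                                Biostrings::DNAStringSet(c(chrX = "ACGT"))),
               "absent")
})

test_that("motif scanning matches IUPAC consensus with overlaps", {
  cat1 <- data.frame(name = "CGTCA-motif", consensus = "CGTCA",
                     category = "hormone")
  hits <- scan_motifs("AAACGTCAAA", cat1)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$offset, 4L)
  expect_equal(fw$match, "CGTCA")
  expect_equal(nrow(scan_motifs("TTTTTTTT", cat1)), 0L)
  # degenerate consensus expands; overlapping hits are all reported
  cat2 <- data.frame(name = "m", consensus = "RAA", category = "x")
  h2 <- scan_motifs("GAAAA", cat2, both_strands = FALSE)
  expect_equal(h2$offset, c(1L, 2L, 3L))
  # N in the sequence never matches a non-N consensus symbol
  h3 <- scan_motifs("AANAA", data.frame(name = "m", consensus = "AAA",
                                        category = "x"),
                    both_strands = FALSE)
  expect_equal(nrow(h3), 0L)
  expect_error(scan_motifs("ACGT", data.frame(name = "bad",
                                              consensus = "ACQT",
                                              category = "x")),
               class = "introcand_catalog_error")
})

test_that("scanning agrees with a brute-force oracle on random sequence", {
  set.seed(8)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  catalog <- read_motif_catalog()
  hits <- scan_motifs(seq, catalog)
  for (i in seq_len(nrow(catalog))) {
    fw <- sort(hits$offset[hits$motif == catalog$name[i] &
                             hits$strand == "+"])
    expect_equal(fw, oracle_scan(seq, catalog$consensus[i]),
                 info = catalog$name[i])
    rv <- sort(hits$offset[hits$motif == catalog$name[i] &
                             hits$strand == "-"])
    expect_equal(rv, oracle_scan(seq, oracle_revcomp(catalog$consensus[i])),
                 info = paste(catalog$name[i], "rev"))
  }
})

test_that("reverse-complementing the sequence mirrors the hit set", {
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  catalog <- read_motif_catalog()
  h1 <- scan_motifs(seq, catalog)
  h2 <- scan_motifs(oracle_revcomp(seq), catalog)
  w <- nchar(catalog$consensus)[match(h1$motif, catalog$name)]
  mirrored <- data.frame(motif = h1$motif,
                         offset = 500L - (h1$offset + w - 1L) + 1L,
                         strand = ifelse(h1$strand == "+", "-", "+"))
  key <- function(d) sort(paste(d$motif, d$offset, d$strand))
  expect_equal(key(mirrored), key(h2))
})

test_that("promoter comparison counts mutated motif footprints", {
  catalog <- data.frame(name = c("CGTCA-motif", "HSE"),
                        consensus = c("CGTCA", "AAAAAATTTC"),
                        category = c("hormone", "environmental_stress"))
  a <- "GGGGGCGTCAGGGGGGGGGG"
  expect_equal(compare_promoters(a, a, catalog)$mutated_total, 0L)
  # substitution inside the only hit footprint
  b <- sub("CGTCA", "CGACA", a)
  cmp <- compare_promoters(a, b, catalog)
  expect_equal(cmp$mutated_total, 1L)
  expect_equal(cmp$per_motif$count_a[cmp$per_motif$motif == "CGTCA-motif"],
               1L)
  # a hit present in exactly one sequence counts as mutated
  c2 <- paste0(a, "CGTCA")
  cmp2 <- compare_promoters(a, c2, catalog)
  expect_gte(cmp2$mutated_total, 1L)
  # substitutions outside every footprint do not count
  d <- paste0("TTTTT", substr(a, 6, nchar(a)))
  expect_equal(compare_promoters(a, d, catalog)$mutated_total, 0L)
  # no HSE consensus in either sequence
  expect_false(cmp$hse_present_a)
  expect_false(cmp$hse_present_b)
  expect_error(compare_promoters("", a, catalog), "empty")
})

test_that("adding a motif to the catalog never removes hits", {
  set.seed(10)
  seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
  catalog <- read_motif_catalog()
  h1 <- scan_motifs(seq, catalog[1:5, ])
  h2 <- scan_motifs(seq, rbind(catalog[1:5, ],
                               data.frame(name = "new", consensus = "ACGT",
                                          category = "x")))
  expect_gte(nrow(h2), nrow(h1))
  expect_true(all(paste(h1$motif, h1$offset, h1$strand) %in%
                    paste(h2$motif, h2$offset, h2$strand)))
})

test_that("promoter FASTA export round-trips through Biostrings", {
  d <- shared_sim()
  ids <- utils::head(d$genes$genes$gene_id, 3)
  f <- withr::local_tempfile(fileext = ".fa")
  write_promoter_fasta(d$genes, ids, d$reference, f)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(names(back), ids)
  expect_equal(as.character(back[[1]]),
               as.character(extract_promoter(d$genes, ids[1],
                                             d$reference)))
})
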
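# Shared simulated dataset, built once per test run (the full-scale
# generator takes a noticeable fraction of the suite's runtime).
.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$data)) {
    .sim_cache$data <- simulate_dataset(sim_config(seed = 101))
  }
  .sim_cache$data
}

# A small, fast configuration for smoke tests.
small_config <- function(seed = 11) {
  sim_config(n_chromosomes = 2, chrom_length_bp = 2e6,
             n_genes_per_chrom = 6,
             introgression_segments = data.frame(chrom = "chr2",
                                                 start = 200001,
                                                 end = 1800000),
             n_panel_sites_per_chrom = 120, seed = seed)
}

# A minimal hand-built locus: one chromosome, one or two genes with a
# known sequence, used by the effect-annotation unit tests.
# layout (1-based):   1..30 pad | gene | pad
# plus-strand gene: 5'UTR 31..36, exon1 CDS 37..45, intron 46..57,
# exon2 CDS 58..66, 3'UTR 67..72  (CDS = 18 bases = 6 codons)
tiny_locus <- function(strand = "+") {
  utr5 <- "TTTTTT"; utr3 <- "CCCCCC"
  cds1 <- "ATGGCTTGC"          # Met Ala Cys
  intron <- "GTAAGTATACAG"
  cds2 <- "TTCAAGTAA"          # Phe Lys Stop
  pad <- strrep("ACGT", 50)    # 200 bp pads either side
  if (strand == "+") {
    body <- paste0(utr5, cds1, intron, cds2, utr3)
  } else {
    body <- oracle_revcomp(paste0(utr5, cds1, intron, cds2, utr3))
  }
  seq <- paste0(substr(pad, 1, 30), body, pad)
  tx_start <- 31L
  tx_end <- 31L + nchar(body) - 1L
  if (strand == "+") {
    exons <- data.frame(gene_id = "g1", type = "exon",
                        start = c(31L, 58L), end = c(45L, 66L + 6L))
    cds <- data.frame(gene_id = "g1", type = "cds",
                      start = c(37L, 58L), end = c(45L, 66L))
  } else {
    # mirrored coordinates: transcript runs right to left
    exons <- data.frame(gene_id = "g1", type = "exon",
                        start = c(tx_start, tx_start + 6L + 9L + 12L),
                        end = c(tx_start + 6L + 9L - 1L, tx_end))
    cds <- data.frame(gene_id = "g1", type = "cds",
                      start = c(tx_start + 6L, tx_start + 6L + 9L + 12L),
                      end = c(tx_start + 6L + 9L - 1L,
                              tx_start + 6L + 9L + 12L + 9L - 1L))
  }
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
               tx_start = tx_start, tx_end = tx_end,
               description = "Heat shock protein 70 kDa",
               stringsAsFactors = FALSE),
    rbind(exons, cds))
  list(gm = gm, seq = Biostrings::DNAString(seq),
       genome = Biostrings::DNAStringSet(stats::setNames(seq, "chr1")))
}

# Minimal single-exon coding gene (60 bp CDS) used by the fusion test.
build_gene_for_test <- function(strand, start, id = "g") {
  end <- start + 59L
  list(gene = data.frame(gene_id = id, chrom = "chr1", strand = strand,
                         tx_start = start, tx_end = end,
                         description = "test", stringsAsFactors = FALSE),
       features = data.frame(gene_id = id, type = c("exon", "cds"),
                             start = start, end = end,
                             stringsAsFactors = FALSE))
}

tiny_variant <- function(pos, ref, alt, chrom = "chr1") {
  variant_records(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  qual = 50, depth = 30, genotype = "hom_alt")
}
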
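test_that("configuration invariants are enforced with the field named", {
  expect_error(sim_config(background_rate = -1), "background_rate")
  expect_error(sim_config(background_rate = 100, introgression_rate = 50),
               "introgression_rate")
  expect_error(sim_config(indel_fraction = 1.2), "indel_fraction")
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(
    sim_config(introgression_segments = data.frame(
      chrom = "chr9", start = 1, end = 10)), "introgression_segments")
  expect_error(
    sim_config(n_chromosomes = 2, chrom_length_bp = 1e6,
               introgression_segments = data.frame(
                 chrom = "chr1", start = 1, end = 2e6)),
    "introgression_segments")
  expect_error(
    sim_config(introgression_segments = data.frame(
      chrom = c("chr1", "chr1"), start = c(1, 5e5), end = c(6e5, 9e5))),
    "overlapping")
  # equal rates are a legal degenerate configuration (no density contrast)
  expect_s3_class(sim_config(background_rate = 50,
                             introgression_rate = 50), "sim_config")
})

test_that("zero background rate confines all variants to the segment", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e6,
                    background_rate = 0, introgression_rate = 400,
                    introgression_segments = data.frame(
                      chrom = "chr1", start = 2e6 + 1, end = 3e6),
                    seed = 4)
  v <- simulate_focal_variants(cfg, seed = 4)
  expect_gt(nrow(v), 0)
  expect_true(all(v$pos >= 2e6 + 1 & v$pos <= 3e6))
})

test_that("total variant count follows the Poisson sum", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 10e6,
                    background_rate = 50, introgression_rate = 1000,
                    introgression_segments = data.frame(
                      chrom = "chr1", start = 2e6 + 1, end = 5e6),
                    seed = 1)
  v <- simulate_focal_variants(cfg, seed = 1)
  expected <- 50 * 17 + 1000 * 3          # rates times Mb
  sd <- sqrt(expected)
  expect_lt(abs(nrow(v) - expected), 4 * sd)
})

test_that("identical configurations write byte-identical files", {
  cfg <- small_config(seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(small_config(seed = 22), dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "focal.vcf"))),
    unname(tools::md5sum(file.path(d3, "focal.vcf")))))
})

test_that("window densities inside truth segments dominate, every seed", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e6,
                    background_rate = 20, introgression_rate = 200,
                    introgression_segments = data.frame(
                      chrom = "chr1", start = 2e6 + 1, end = 4e6),
                    seed = 1)
  for (s in 1:100) {
    v <- simulate_focal_variants(cfg, seed = s)
    w <- count_in_windows(v, c(chr1 = 5e6), region_config())
    inside <- w$start >= 2e6 + 1 & w$end <= 4e6
    tot <- w$snp_count + w$indel_count
    expect_gt(mean(tot[inside]), mean(tot[!inside]))
  }
})

test_that("planted effects round-trip through the annotator", {
  d <- shared_sim()
  pv <- d$truth$planted_variants
  expect_gte(nrow(pv), 500)
  ann <- annotate_variants(pv[, 1:8], d$genes, d$reference)
  akey <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, ann$gene)
  pkey <- paste(pv$chrom, pv$pos, pv$ref, pv$alt, pv$gene_id)
  genic <- pv$intended_effect != "intergenic_variant"
  m <- match(pkey[genic], akey)
  expect_false(anyNA(m))
  expect_equal(ann$effect[m], pv$intended_effect[genic])
  expect_equal(ann$impact[m], pv$intended_impact[genic])
  # intergenic plantings carry no gene and annotate as intergenic
  m2 <- match(paste(pv$chrom, pv$pos, pv$ref, pv$alt)[!genic],
              paste(ann$chrom, ann$pos, ann$ref, ann$alt))
  expect_true(all(ann$effect[m2] == "intergenic_variant"))
})

test_that("planted promoter motifs are recovered by the scanner", {
  d <- shared_sim()
  pm <- d$truth$planted_motifs
  set.seed(1)
  take <- pm[sample(nrow(pm), 25), ]
  for (i in seq_len(nrow(take))) {
    prom <- extract_promoter(d$genes, take$gene_id[i], d$reference)
    hits <- scan_motifs(prom, d$motif_catalog)
    hit <- hits[hits$motif == take$motif[i] &
                  hits$offset == take$offset[i] & hits$strand == "+", ]
    expect_equal(nrow(hit), 1L)
  }
})

test_that("effects impossible for a gene raise an unsatisfiable error", {
  g <- build_gene_for_test("+", 101L, "solo")
  gm <- gene_models(g$gene, g$features)
  seq_chr <- strrep("ACGT", 100)
  expect_error(plant_effect_variants(gm, "solo", seq_chr, "intron_variant"),
               class = "introcand_unsatisfiable")
  expect_error(plant_effect_variants(gm, "solo", seq_chr, "no_such_effect"),
               class = "introcand_unsatisfiable")
})

test_that("the panel clusters by species and the focal row is mosaic", {
  p <- simulate_panel(small_config(seed = 30), seed = 30)
  expect_equal(nrow(p$dosage), 1 + 4 * 3)
  d <- genotype_distance(p$dosage)
  within <- c(d["S_lycopersicum_1", "S_lycopersicum_2"],
              d["S_pimpinellifolium_1", "S_pimpinellifolium_2"])
  between <- d["S_lycopersicum_1", "S_pimpinellifolium_1"]
  expect_true(all(within < between))
  # focal carries the donor haplotype inside the segment: its
  # discordance with a donor accession there is far below its
  # discordance with the cultivated background
  chr2 <- p$sites$chrom == "chr2"
  inseg <- chr2 & p$sites$pos >= 200001 & p$sites$pos <= 1800000
  f <- p$dosage["E42", inseg]
  don <- p$dosage["S_pimpinellifolium_1", inseg]
  bkg <- p$dosage["S_lycopersicum_1", inseg]
  ok <- !is.na(don) & !is.na(bkg)
  expect_lt(mean(f[ok] != don[ok]), mean(f[ok] != bkg[ok]))
})
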
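sim_species_names <- function(n_species) {
  pool <- c("S_lycopersicum", "S_pimpinellifolium", "S_habrochaites",
            "S_pennellii", "S_cheesmaniae", "S_peruvianum", "S_chilense",
            "S_neorickii", "S_galapagense", "S_arcanum", "S_chmielewskii",
            "S_huaylasense", "S_corneliomuelleri")
  if (n_species > length(pool))
    pool <- c(pool, sprintf("S_species%02d", seq_len(n_species)))
  pool[seq_len(n_species)]
}

#' Simulate the multi-species accession panel
#'
#' Draws panel sites per chromosome, per-species haplotypes (each
#' species accumulates alternate alleles at `species_divergence` per
#' site), and per-accession genotypes with accession-level noise and
#' missing calls.  The focal sample carries the cultivated background
#' species' haplotype outside the configured introgression segments and
#' an exact copy of the wild donor's haplotype inside them.
#'
#' @param cfg a [sim_config()].
#' @param genome optional named list of chromosome character strings
#'   for REF alleles.
#' @param focal_name focal sample name (default `"E42"`).
#' @param seed optional seed; by default the current RNG stream is used.
#' @return list with `dosage` (samples x sites), `sites`, `species_of`
#'   (named vector over non-focal samples), `focal`, `donor_species`,
#'   `background_species`.
#' @export
simulate_panel <- function(cfg, genome = NULL, focal_name = "E42",
                           seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_panel(cfg, genome, focal_name)))
  species <- sim_species_names(cfg$n_species)
  background <- species[1]
  donor <- species[2]
  bases <- c("A", "C", "G", "T")
  sites <- list(); hap_rows <- list()
  for (chr in sim_chrom_names(cfg)) {
    pos <- sort(sample.int(cfg$chrom_length_bp - 4L,
                           cfg$n_panel_sites_per_chrom))
    ref <- if (!is.null(genome)) {
      vapply(pos, function(p) substr(genome[[chr]], p, p), character(1))
    } else sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    sites[[chr]] <- data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  n_sites <- nrow(sites)
  # species haplotypes: 1 = alternate allele
  hap <- matrix(stats::rbinom(length(species) * n_sites, 1,
                              cfg$species_divergence),
                nrow = length(species),
                dimnames = list(species, NULL))
  samples <- c(focal_name,
               unlist(lapply(species, function(sp)
                 sprintf("%s_%d", sp, seq_len(cfg$n_accessions_per_species)))))
  species_of <- stats::setNames(
    rep(species, each = cfg$n_accessions_per_species),
    samples[-1])
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = n_sites,
                   dimnames = list(samples, NULL))
  inside <- in_segments(cfg, sites$chrom, sites$pos)
  focal_hap <- ifelse(inside, hap[donor, ], hap[background, ])
  flip <- stats::rbinom(n_sites, 1, cfg$accession_noise) == 1 & !inside
  focal_hap[flip] <- 1L - focal_hap[flip]
  dosage[focal_name, ] <- 2L * focal_hap
  for (sm in samples[-1]) {
    h <- hap[species_of[[sm]], ]
    flip <- stats::rbinom(n_sites, 1, cfg$accession_noise) == 1
    h[flip] <- 1L - h[flip]
    d <- 2L * h
    d[stats::rbinom(n_sites, 1, cfg$missing_rate) == 1] <- NA_integer_
    dosage[sm, ] <- d
  }
  colnames(dosage) <- paste(sites$chrom, sites$pos, sep = ":")
  list(dosage = dosage, sites = sites, species_of = species_of,
       focal = focal_name, donor_species = donor,
       background_species = background)
}

#' Write a panel as a multi-sample VCF v4.2 file
#'
#' @param panel result of [simulate_panel()].
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=introcand")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  samples <- rownames(panel$dosage)
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(panel$sites)), function(i) {
    gts <- vapply(samples, function(sm) {
      d <- panel$dosage[sm, i]
      if (is.na(d)) "./.:.:." else sprintf("%s:99:25", gt_of[d + 1L])
    }, character(1))
    paste(c(panel$sites$chrom[i], panel$sites$pos[i], ".",
            panel$sites$ref[i], panel$sites$alt[i], "100.0", "PASS", ".",
            "GT:GQ:DP", gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

concretize_iupac <- function(consensus) {
  tab <- iupac_table()
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(sym) {
    opts <- tab[[sym]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# Promoter genomic window [lo, hi] for a gene (3 kb upstream).
promoter_window <- function(g, length_bp = 3000) {
  if (g$strand == "+") c(g$tx_start - length_bp, g$tx_start - 1L)
  else c(g$tx_end + 1L, g$tx_end + length_bp)
}

#' Simulate a complete synthetic dataset
#'
#' Generates every input the analysis pipeline consumes, with known
#' ground truth: a reference genome whose gene models carry valid ORFs,
#' promoters with planted cis elements, a focal variant call set
#' (Poisson background/introgression densities plus planted
#' effect-known coding variants), a donor call set (the introgressed
#' alleles), a multi-species panel, a QTL table and the motif catalog.
#'
#' All randomness flows from `cfg$seed`; the same configuration yields
#' byte-identical output files.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, all files are
#'   written there (reference.fa, genes.gff3, focal.vcf, donor.vcf,
#'   panel.vcf, qtls.tsv, motif_catalog.tsv, truth.json).
#' @return list with `reference` (DNAStringSet), `genes`
#'   ([gene_models]), `focal`, `donor` (variant records), `panel`,
#'   `qtls`, `motif_catalog`, `truth`, and `paths` when `dir` is given.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, simulate_dataset_impl(cfg, dir))
}

simulate_dataset_impl <- function(cfg, dir) {
  bases <- c("A", "C", "G", "T")
  chroms <- sim_chrom_names(cfg)
  gm <- simulate_gene_models(cfg)
  catalog <- read_motif_catalog()

  # --- reference genome: random bases, then ORF patches, then motifs ---
  genome_chr <- list()
  planted_motifs <- list()
  for (chr in chroms) {
    v <- sample(bases, cfg$chrom_length_bp, replace = TRUE)
    gs <- gm$genes[gm$genes$chrom == chr, ]
    for (gi in seq_len(nrow(gs))) {
      id <- gs$gene_id[gi]
      L <- cds_length(gm, id)
      n_cod <- L %/% 3L
      internal <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))
      orf <- paste0("ATG",
                    paste(sample(internal, n_cod - 2L, replace = TRUE),
                          collapse = ""),
                    "TAA")
      orf_gen <- if (gs$strand[gi] == "+") orf else revcomp_chr(orf)
      iv <- gene_intervals(gm, id, "cds")
      at <- 1L
      for (k in seq_len(nrow(iv))) {
        w <- iv[k, "end"] - iv[k, "start"] + 1L
        v[iv[k, "start"]:iv[k, "end"]] <-
          strsplit(substr(orf_gen, at, at + w - 1L), "")[[1]]
        at <- at + w
      }
      # plant 2-4 non-HSE cis elements in the promoter
      cat_ok <- catalog[!grepl("HSE", catalog$name, ignore.case = TRUE), ]
      n_m <- sample(2:4, 1)
      picks <- cat_ok[sample(nrow(cat_ok), n_m), ]
      offsets <- sort(sample(seq(100, 2800, by = 60), n_m))
      win <- promoter_window(gs[gi, ])
      for (mi in seq_len(n_m)) {
        inst <- concretize_iupac(picks$consensus[mi])
        wlen <- nchar(inst)
        o <- offsets[mi]
        if (gs$strand[gi] == "+") {
          gpos <- win[1] + o - 1L
          v[gpos:(gpos + wlen - 1L)] <- strsplit(inst, "")[[1]]
        } else {
          ghi <- win[2] - o + 1L
          glo <- ghi - wlen + 1L
          v[glo:ghi] <- strsplit(revcomp_chr(inst), "")[[1]]
        }
        planted_motifs[[length(planted_motifs) + 1L]] <-
          data.frame(gene_id = id, motif = picks$name[mi], offset = o,
                     stringsAsFactors = FALSE)
      }
    }
    genome_chr[[chr]] <- paste(v, collapse = "")
  }
  planted_motifs <- do.call(rbind, planted_motifs)

  # --- QTL table -----------------------------------------------------------
  kw_sel <- keyword_select(gm)
  kw_ids <- unique(c(kw_sel$heat$gene_id, kw_sel$reproduction$gene_id))
  gtab <- gm$genes
  seg_of_gene <- in_segments(cfg, gtab$chrom, gtab$tx_start) &
    in_segments(cfg, gtab$chrom, gtab$tx_end)
  kw_outside <- gtab$gene_id[gtab$gene_id %in% kw_ids & !seg_of_gene]
  seg_chroms <- unique(cfg$introgression_segments$chrom)
  kw_outside <- kw_outside[!gtab$chrom[match(kw_outside, gtab$gene_id)] %in%
                             seg_chroms]
  flower_genes <- utils::head(kw_outside, 2)
  decoy_gene <- if (length(kw_outside) > 2) kw_outside[3] else character()
  mk_qtl <- function(id, trait_class, gene_id, trait = trait_class) {
    gi <- gtab[gtab$gene_id == gene_id, ]
    data.frame(qtl_id = id, trait = trait, trait_class = trait_class,
               chrom = gi$chrom,
               start = max(1, gi$tx_start - 20000),
               end = gi$tx_end + 20000,
               source = "synthetic", stringsAsFactors = FALSE)
  }
  qtls <- list()
  for (i in seq_along(flower_genes)) {
    qtls[[length(qtls) + 1L]] <-
      mk_qtl(sprintf("FLN_syn%02d", i), "Flower number", flower_genes[i])
  }
  if (length(decoy_gene) == 1) {
    qtls[[length(qtls) + 1L]] <-
      mk_qtl("FRS_syn01", "Fruit set", decoy_gene)
  }
  neutral_classes <- c("Fruit number", "Pollen number", "Anther length",
                       "Stigma length/protrusion/exertion",
                       "Inflorescence with a single cyme", "Pollen viability")
  for (chr in chroms) {
    st <- sample.int(max(1L, as.integer(cfg$chrom_length_bp * 0.8)), 2,
                     replace = TRUE)
    for (k in 1:2) {
      cls <- neutral_classes[(length(qtls) %% length(neutral_classes)) + 1]
      qtls[[length(qtls) + 1L]] <- data.frame(
        qtl_id = sprintf("Q_%s_%d", chr, k),
        trait = cls, trait_class = cls,
        chrom = chr, start = st[k],
        end = min(cfg$chrom_length_bp, st[k] + sample(5:15, 1) * 1e5),
        source = "synthetic", stringsAsFactors = FALSE)
    }
  }
  qtls <- do.call(rbind, qtls)

  # --- planted effect variants --------------------------------------------
  high_rot <- c("frameshift_variant", "stop_gained", "stop_lost",
                "splice_donor_variant", "splice_acceptor_variant")
  mod_rot <- c("missense_variant", "conservative_inframe_deletion",
               "disruptive_inframe_deletion", "conservative_inframe_insertion",
               "disruptive_inframe_insertion")
  all_eff <- plantable_effects()
  planted <- list()
  intended <- character()
  ri_h <- 0L; ri_m <- 0L; ri_a <- 0L
  for (i in seq_len(nrow(gtab))) {
    id <- gtab$gene_id[i]
    chr <- gtab$chrom[i]
    is_kw <- id %in% kw_ids
    inside <- seg_of_gene[i]
    effs <- if (is_kw && inside) {
      ri_h <- ri_h + 1L; ri_m <- ri_m + 1L
      c(high_rot[(ri_h - 1L) %% length(high_rot) + 1L],
        mod_rot[(ri_m - 1L) %% length(mod_rot) + 1L])
    } else if (is_kw && id %in% flower_genes) {
      ri_m <- ri_m + 1L
      mod_rot[(ri_m - 1L) %% length(mod_rot) + 1L]
    } else if (is_kw && id %in% decoy_gene) {
      ri_h <- ri_h + 1L
      high_rot[(ri_h - 1L) %% length(high_rot) + 1L]
    } else if (is_kw) {
      c("synonymous_variant", "intron_variant")
    } else {
      idx <- (ri_a + seq_len(5L) - 1L) %% length(all_eff) + 1L
      ri_a <- ri_a + 5L
      all_eff[idx]
    }
    planted[[length(planted) + 1L]] <-
      plant_effect_variants(gm, id, genome_chr[[chr]], unique(effs))
    if (is_kw && (inside || id %in% flower_genes))
      intended <- c(intended, id)
  }
  planted <- do.call(rbind, planted)

  # --- focal call set ------------------------------------------------------
  mask <- data.frame(chrom = gtab$chrom, start = gtab$tx_start,
                     end = gtab$tx_end, stringsAsFactors = FALSE)
  density <- simulate_focal_variants(cfg, genome = genome_chr, mask = mask)
  pl_rec <- planted[, c("chrom", "pos", "ref", "alt", "qual", "depth",
                        "genotype", "vclass")]
  clash <- paste(density$chrom, density$pos) %in%
    paste(pl_rec$chrom, pl_rec$pos)
  focal <- rbind(density[!clash, ], pl_rec)
  focal <- focal[order(focal$chrom, focal$pos), ]
  rownames(focal) <- NULL

  # --- donor call set: the introgressed alleles ----------------------------
  donor <- focal[in_segments(cfg, focal$chrom, focal$pos), , drop = FALSE]
  rownames(donor) <- NULL

  # --- panel ---------------------------------------------------------------
  panel <- simulate_panel(cfg, genome = genome_chr)

  truth <- list(
    segments = cfg$introgression_segments,
    planted_variants = planted,
    donor_variant_keys = paste(donor$chrom, donor$pos, donor$ref,
                               donor$alt, sep = ":"),
    planted_motifs = planted_motifs,
    keyword_genes = kw_ids,
    flower_qtl_genes = flower_genes,
    intended_candidates = sort(unique(intended)),
    donor_species = panel$donor_species,
    background_species = panel$background_species,
    species_of = as.list(panel$species_of),
    seed = cfg$seed)

  reference <- Biostrings::DNAStringSet(unlist(genome_chr))
  names(reference) <- chroms

  out <- list(reference = reference, genes = gm, focal = focal,
              donor = donor, panel = panel, qtls = qtls,
              motif_catalog = catalog, truth = truth, config = cfg)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- list(
      reference = file.path(dir, "reference.fa"),
      genes = file.path(dir, "genes.gff3"),
      focal = file.path(dir, "focal.vcf"),
      donor = file.path(dir, "donor.vcf"),
      panel = file.path(dir, "panel.vcf"),
      qtls = file.path(dir, "qtls.tsv"),
      motif_catalog = file.path(dir, "motif_catalog.tsv"),
      truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(reference, p$reference, width = 80)
    write_gene_models_gff3(gm, p$genes)
    cl <- sim_chrom_lengths(cfg)
    write_variants_vcf(focal, p$focal, sample_name = panel$focal,
                       contig_lengths = cl)
    write_variants_vcf(donor, p$donor, sample_name = "wild_donor",
                       contig_lengths = cl)
    write_panel_vcf(panel, p$panel, contig_lengths = cl)
    write_tsv_plain(qtls, p$qtls)
    write_tsv_plain(catalog, p$motif_catalog)
    jsonlite::write_json(truth, p$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
    out$paths <- p
  }
  out
}
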
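#' Simulation configuration
#'
#' Parameters of the synthetic mosaic-genome generator.  The defaults
#' define the package's reference study conditions: a 6 x 10 Mb genome
#' whose chromosomes 2 and 5 carry one wild-donor introgression each
#' (covering ~70% of their chromosome, so those chromosomes cluster
#' with the donor species), a 20-fold variant-density contrast between
#' introgressed and background sequence, an InDel fraction of 0.12, and
#' a 4-species accession panel.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (all equal).
#' @param n_genes_per_chrom gene models per chromosome.
#' @param introgression_segments data.frame with chrom, start, end
#'   (1-based inclusive) marking introgressed truth segments.
#' @param background_rate expected variants per Mb outside segments
#'   (Poisson mean).
#' @param introgression_rate expected variants per Mb inside segments.
#' @param indel_fraction proportion of variants that are InDels.
#' @param n_species number of panel species (>= 2; the first is the
#'   cultivated background, the second the wild donor).
#' @param n_accessions_per_species accessions per species.
#' @param species_divergence per-site alternate-allele probability per
#'   species branch.
#' @param n_panel_sites_per_chrom panel sites per chromosome.
#' @param accession_noise per-site flip probability within a species.
#' @param missing_rate per-call missing-genotype probability in the
#'   panel.
#' @param seed integer seed driving all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 6,
                       chrom_length_bp = 10e6,
                       n_genes_per_chrom = 30,
                       introgression_segments = NULL,
                       background_rate = 50,
                       introgression_rate = 1000,
                       indel_fraction = 0.12,
                       n_species = 4,
                       n_accessions_per_species = 3,
                       species_divergence = 0.2,
                       n_panel_sites_per_chrom = 300,
                       accession_noise = 0.02,
                       missing_rate = 0.02,
                       seed = 1) {
  if (is.null(introgression_segments)) {
    introgression_segments <- data.frame(
      chrom = c("chr2", "chr5"),
      start = c(2000001, 1000001),
      end = c(9000000, 8000000),
      stringsAsFactors = FALSE)
    introgression_segments <- introgression_segments[
      introgression_segments$chrom %in%
        paste0("chr", seq_len(n_chromosomes)), , drop = FALSE]
  }
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_genes_per_chrom = as.integer(n_genes_per_chrom),
              introgression_segments = introgression_segments,
              background_rate = background_rate,
              introgression_rate = introgression_rate,
              indel_fraction = indel_fraction,
              n_species = as.integer(n_species),
              n_accessions_per_species = as.integer(n_accessions_per_species),
              species_divergence = species_divergence,
              n_panel_sites_per_chrom = as.integer(n_panel_sites_per_chrom),
              accession_noise = accession_noise,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_chromosomes < 1) stop_config("invalid field n_chromosomes")
  if (cfg$chrom_length_bp < 1e4) stop_config("invalid field chrom_length_bp")
  if (cfg$n_genes_per_chrom < 1) stop_config("invalid field n_genes_per_chrom")
  if (cfg$background_rate < 0) stop_config("invalid field background_rate")
  if (cfg$introgression_rate < cfg$background_rate)
    stop_config(
      "invalid field introgression_rate: must be >= background_rate")
  if (cfg$indel_fraction < 0 || cfg$indel_fraction > 1)
    stop_config("invalid field indel_fraction: must be in [0, 1]")
  if (cfg$n_species < 2) stop_config("invalid field n_species: need >= 2")
  if (cfg$n_accessions_per_species < 1)
    stop_config("invalid field n_accessions_per_species")
  if (cfg$species_divergence < 0 || cfg$species_divergence > 0.5)
    stop_config("invalid field species_divergence: must be in [0, 0.5]")
  seg <- cfg$introgression_segments
  if (nrow(seg) > 0) {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    if (!all(seg$chrom %in% chroms))
      stop_config("invalid field introgression_segments: unknown chromosome")
    if (any(seg$start < 1) || any(seg$end > cfg$chrom_length_bp) ||
        any(seg$start >= seg$end))
      stop_config("invalid field introgression_segments: out of bounds")
    for (chr in unique(seg$chrom)) {
      s <- seg[seg$chrom == chr, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop_config("invalid field introgression_segments: overlapping")
    }
  }
  invisible(cfg)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))

#' Chromosome lengths of a simulation configuration
#' @param cfg a [sim_config()].
#' @return named numeric vector.
#' @export
sim_chrom_lengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chromosomes),
                  sim_chrom_names(cfg))
}

in_segments <- function(cfg, chrom, pos) {
  seg <- cfg$introgression_segments
  if (nrow(seg) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(seg))) {
    out <- out | (chrom == seg$chrom[i] & pos >= seg$start[i] &
                    pos <= seg$end[i])
  }
  out
}

# Draw Poisson-process variant positions for one chromosome: rate_bg
# outside the chromosome's segments, rate_in inside.
draw_positions <- function(len, segments, rate_bg, rate_in) {
  pos <- integer(0)
  segs <- segments[order(segments$start), , drop = FALSE]
  bounds <- c(0, as.vector(t(cbind(segs$start - 1, segs$end))), len)
  # alternating background / introgressed intervals
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k] + 1
    hi <- bounds[k + 1]
    if (hi < lo) next
    rate <- if (k %% 2 == 0) rate_in else rate_bg
    n <- stats::rpois(1, rate * (hi - lo + 1) / 1e6)
    if (n > 0) pos <- c(pos, lo - 1L + sample.int(hi - lo + 1, n,
                                                  replace = TRUE))
  }
  sort(unique(pos))
}

#' Simulate the focal genotype's variant calls
#'
#' Places variants as a Poisson process at `background_rate` per Mb
#' outside the configured introgression segments and
#' `introgression_rate` inside, assigns SNP/InDel class at
#' `indel_fraction`, and draws quality/depth/genotype values typical of
#' a resequencing call set (a small fraction of calls is low-quality,
#' heterozygous or missing, so the filtering step has work to do).
#' Positions overlapping `mask` intervals (typically gene bodies, whose
#' coding variants the full generator plants explicitly) are dropped.
#'
#' @param cfg a [sim_config()].
#' @param genome optional named list of chromosome sequences (character
#'   strings); when given, REF alleles are read from it, otherwise they
#'   are drawn at random.
#' @param mask optional data.frame chrom, start, end of excluded spans.
#' @param seed optional seed; by default the current RNG stream is used
#'   (so [simulate_dataset()] drives everything from one seed).
#' @return A variant-record `data.frame`.
#' @export
simulate_focal_variants <- function(cfg, genome = NULL, mask = NULL,
                                    seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_focal_variants(cfg, genome, mask)))
  bases <- c("A", "C", "G", "T")
  all_rows <- list()
  for (chr in sim_chrom_names(cfg)) {
    segs <- cfg$introgression_segments
    segs <- segs[segs$chrom == chr, , drop = FALSE]
    pos <- draw_positions(cfg$chrom_length_bp, segs,
                          cfg$background_rate, cfg$introgression_rate)
    # leave room for deletion alleles at the chromosome end
    pos <- pos[pos <= cfg$chrom_length_bp - 4]
    if (!is.null(mask)) {
      mk <- mask[mask$chrom == chr, , drop = FALSE]
      if (nrow(mk) > 0) {
        drop <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(mk)))
          drop <- drop | (pos >= mk$start[i] & pos <= mk$end[i])
        pos <- pos[!drop]
      }
    }
    n <- length(pos)
    if (n == 0) next
    seq_chr <- if (!is.null(genome)) genome[[chr]] else NULL
    base_at <- function(p, w = 1L) {
      if (is.null(seq_chr)) paste(sample(bases, w, replace = TRUE),
                                  collapse = "")
      else substr(seq_chr, p, p + w - 1L)
    }
    is_indel <- stats::runif(n) < cfg$indel_fraction
    ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      if (!is_indel[i]) {
        r <- base_at(pos[i])
        ref[i] <- r
        alt[i] <- sample(setdiff(bases, r), 1)
      } else if (stats::runif(1) < 0.5) {  # insertion
        r <- base_at(pos[i])
        ref[i] <- r
        alt[i] <- paste0(r, paste(sample(bases, sample(1:3, 1),
                                         replace = TRUE), collapse = ""))
      } else {                             # deletion
        w <- sample(1:3, 1)
        ref[i] <- base_at(pos[i], w + 1L)
        alt[i] <- substr(ref[i], 1, 1)
      }
    }
    qual <- stats::runif(n, 20, 60)
    lowq <- stats::runif(n) < 0.03
    qual[lowq] <- stats::runif(sum(lowq), 0, 14.9)
    geno <- sample(c("hom_alt", "het", "missing"), n, replace = TRUE,
                   prob = c(0.93, 0.05, 0.02))
    all_rows[[chr]] <- variant_records(chrom = chr, pos = pos, ref = ref,
                                       alt = alt, qual = qual,
                                       depth = stats::rpois(n, 30),
                                       genotype = geno)
  }
  if (length(all_rows) == 0)
    return(variant_records("chr1", 1, "A", "C")[0, ])
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  out
}

# --- gene model generation -------------------------------------------------

sim_keyword_pool <- function() {
  c("Heat shock protein 70 kDa",
    "Small heat shock protein 20",
    "Heat stress transcription factor A-5",
    "DNAJ heat shock N-terminal domain-containing protein",
    "Flowering locus T",
    "Terminal flower 1",
    "Pollen-specific LRR extensin-like protein",
    "Anther-specific protein LAT52")
}

sim_neutral_pool <- function() {
  c("Ubiquitin ligase", "Cytochrome P450", "Ribosomal protein L10",
    "ABC transporter family protein", "Serine/threonine protein kinase",
    "Pectinesterase", "Aquaporin PIP2", "Unknown protein")
}

# Block layout in transcript order: (exon index, kind, length).
gene_blocks <- function(three_exons) {
  if (three_exons) {
    list(c(1, "utr5", 120), c(1, "cds", 240), c(0, "intron", 400),
         c(2, "cds", 330), c(0, "intron", 380),
         c(3, "cds", 333), c(3, "utr3", 150))
  } else {
    list(c(1, "utr5", 120), c(1, "cds", 300), c(0, "intron", 420),
         c(2, "cds", 402), c(2, "utr3", 150))
  }
}

# Build one gene's rows (genes + features) from a transcript-order block
# layout laid down at genomic anchor `s`.
build_gene <- function(gene_id, chrom, strand, s, three_exons, description) {
  blocks <- gene_blocks(three_exons)
  if (strand == "-") blocks <- rev(blocks)
  feat <- list()
  exon_spans <- list()
  at <- s
  for (b in blocks) {
    len <- as.integer(b[3])
    iv <- c(at, at + len - 1L)
    kind <- b[2]
    exid <- b[1]
    if (kind != "intron") {
      exon_spans[[exid]] <- range(c(exon_spans[[exid]], iv))
      if (kind == "cds")
        feat[[length(feat) + 1L]] <- data.frame(
          gene_id = gene_id, type = "cds", start = iv[1], end = iv[2],
          stringsAsFactors = FALSE)
    }
    at <- at + len
  }
  tx_end <- at - 1L
  exon_rows <- lapply(exon_spans[!vapply(exon_spans, is.null, TRUE)],
                      function(sp) data.frame(gene_id = gene_id,
                                              type = "exon",
                                              start = sp[1], end = sp[2],
                                              stringsAsFactors = FALSE))
  list(gene = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         tx_start = s, tx_end = tx_end,
                         description = description,
                         stringsAsFactors = FALSE),
       features = do.call(rbind, c(feat, exon_rows)))
}

#' Generate the synthetic gene models
#'
#' Lays out `n_genes_per_chrom` gene models per chromosome on a regular
#' grid (promoters and flanks never overlap a neighbouring gene),
#' alternating strand and 2/3-exon structures; descriptions alternate
#' between a keyword pool (heat/HSP/HSF/flowering/pollen/anther
#' vocabulary) and a neutral pool.
#'
#' @param cfg a [sim_config()].
#' @return A [gene_models] object.
#' @export
simulate_gene_models <- function(cfg) {
  kw <- sim_keyword_pool(); nt <- sim_neutral_pool()
  genes <- list(); feats <- list()
  margin <- 60000
  for (ci in seq_len(cfg$n_chromosomes)) {
    chr <- paste0("chr", ci)
    slot <- floor((cfg$chrom_length_bp - 2 * margin) / cfg$n_genes_per_chrom)
    for (gi in seq_len(cfg$n_genes_per_chrom)) {
      id <- sprintf("%s_g%03d", chr, gi)
      s <- as.integer(margin + (gi - 1) * slot + 20000)
      strand <- if (gi %% 2 == 0) "-" else "+"
      three <- (gi %% 3) == 0
      is_kw <- gi %% 2 == 1
      pool <- if (is_kw) kw else nt
      desc <- pool[((gi - 1) %/% 2) %% length(pool) + 1]
      g <- build_gene(id, chr, strand, s, three, desc)
      genes[[length(genes) + 1L]] <- g$gene
      feats[[length(feats) + 1L]] <- g$features
    }
  }
  gene_models(do.call(rbind, genes), do.call(rbind, feats))
}

# Inverse of genomic_to_cds: genomic position of CDS coordinate `cpos`.
cds_to_genomic <- function(gm, gene_id, cpos) {
  iv <- gene_intervals(gm, gene_id, "cds")
  total <- sum(iv[, "end"] - iv[, "start"] + 1L)
  strand <- gene_row(gm, gene_id)$strand
  fwd <- if (strand == "+") cpos else total - cpos + 1L
  acc <- 0L
  for (k in seq_len(nrow(iv))) {
    w <- iv[k, "end"] - iv[k, "start"] + 1L
    if (fwd <= acc + w) return(iv[k, "start"] + (fwd - acc - 1L))
    acc <- acc + w
  }
  stop_data("CDS coordinate %d out of range for gene '%s'", cpos, gene_id)
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

plantable_effects <- function() {
  c("synonymous_variant", "missense_variant", "stop_gained", "stop_lost",
    "frameshift_variant",
    "conservative_inframe_deletion", "disruptive_inframe_deletion",
    "conservative_inframe_insertion", "disruptive_inframe_insertion",
    "intron_variant", "splice_donor_variant", "splice_acceptor_variant",
    "splice_region_variant", "five_prime_UTR_variant",
    "three_prime_UTR_variant", "upstream_gene_variant",
    "downstream_gene_variant", "intergenic_variant")
}

#' Plant variants with known effects in a gene
#'
#' Constructs, for each requested effect term, a variant whose
#' re-annotation by [annotate_effect()] yields exactly that term.  The
#' construction path is independent of the annotation path (it builds
#' codon edits and boundary-placed indels directly from the gene
#' layout), so round-trip agreement is a meaningful check.
#'
#' @param gm a [gene_models] object.
#' @param gene_id target gene.
#' @param chrom_seq the gene's chromosome sequence (character string or
#'   `DNAString`).
#' @param effects character vector of requested effect terms (see
#'   `plantable_effects`).
#' @param flank_bp flank distance used for up/down/intergenic placement.
#' @return variant-record data.frame with extra columns `gene_id`,
#'   `intended_effect`, `intended_impact`.
#' @export
plant_effect_variants <- function(gm, gene_id, chrom_seq, effects,
                                  flank_bp = 5000) {
  s <- if (is.character(chrom_seq)) chrom_seq else as.character(chrom_seq)
  g <- gene_row(gm, gene_id)
  strand <- g$strand
  iv <- gene_intervals(gm, gene_id, "cds")
  ex <- gene_intervals(gm, gene_id, "exon")
  if (nrow(iv) == 0)
    stop_data("gene '%s' has no CDS", gene_id,
              class = "introcand_unsatisfiable")
  cdsseq <- cds_sequence_chr(gm, gene_id, s)
  n_codons <- nchar(cdsseq) %/% 3L
  bad <- setdiff(effects, plantable_effects())
  if (length(bad) > 0)
    stop_data("unsupported effect term(s): %s", paste(bad, collapse = ", "),
              class = "introcand_unsatisfiable")
  needs_intron <- c("intron_variant", "splice_donor_variant",
                    "splice_acceptor_variant", "splice_region_variant")
  if (nrow(ex) < 2 && any(effects %in% needs_intron))
    stop_data("gene '%s' has no intron; cannot plant %s", gene_id,
              paste(intersect(effects, needs_intron), collapse = ", "),
              class = "introcand_unsatisfiable")

  codon_at <- function(k) substr(cdsseq, (k - 1) * 3 + 1, k * 3)
  bases <- c("A", "C", "G", "T")
  snp_at_cds <- function(cpos, tx_alt) {
    gp <- cds_to_genomic(gm, gene_id, cpos)
    ref <- substr(s, gp, gp)
    alt <- if (strand == "+") tx_alt else comp_base(tx_alt)
    list(pos = gp, ref = ref, alt = alt)
  }
  # cursor over codons so successive plantings in one gene never touch
  # overlapping bases (each consumer advances it past the codons it used)
  cursor <- 3L
  # codon whose 3 bases are genomically contiguous and whose neighbours
  # share the interval (safe for codon-window indels)
  interior_codon <- function(offset = 0L, from = cursor) {
    for (k in from:(n_codons - 3)) {
      gp <- vapply((k - 2) * 3 + (-2:4) + offset, function(cp)
        cds_to_genomic(gm, gene_id, cp), numeric(1))
      if (all(abs(diff(gp)) == 1)) return(k)
    }
    stop_data("no interior codon available in gene '%s'", gene_id,
              class = "introcand_unsatisfiable")
  }
  first_intron <- function() {
    c(start = unname(ex[1, "end"] + 1L), end = unname(ex[2, "start"] - 1L))
  }

  rows <- list()
  add <- function(pos, ref, alt, effect) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = g$chrom, pos = as.integer(pos), ref = ref, alt = alt,
      qual = 50, depth = 30, genotype = "hom_alt",
      vclass = if (nchar(ref) == 1 && nchar(alt) == 1) "SNP" else "InDel",
      gene_id = gene_id, intended_effect = effect,
      intended_impact = unname(effect_impact_map()[effect]),
      stringsAsFactors = FALSE)
  }

  for (eff in effects) {
    if (eff == "synonymous_variant") {
      done <- FALSE
      for (k in cursor:(n_codons - 2)) {
        cod <- codon_at(k)
        for (b in setdiff(bases, substr(cod, 3, 3))) {
          new <- cod; substr(new, 3, 3) <- b
          if (translate_codon(new) == translate_codon(cod) &&
              translate_codon(cod) != "*") {
            v <- snp_at_cds((k - 1) * 3 + 3, b); done <- TRUE
            cursor <- k + 2L
            add(v$pos, v$ref, v$alt, eff); break
          }
        }
        if (done) break
      }
      if (!done) stop_data("cannot plant synonymous variant in '%s'",
                           gene_id, class = "introcand_unsatisfiable")
    } else if (eff == "missense_variant") {
      done <- FALSE
      for (k in cursor:(n_codons - 2)) {
        cod <- codon_at(k)
        if (translate_codon(cod) == "*") next
        for (p in 1:3) {
          if (done) break
          for (b in setdiff(bases, substr(cod, p, p))) {
            new <- cod; substr(new, p, p) <- b
            aa <- translate_codon(new)
            if (aa != "*" && aa != translate_codon(cod)) {
              v <- snp_at_cds((k - 1) * 3 + p, b); done <- TRUE
              cursor <- k + 2L
              add(v$pos, v$ref, v$alt, eff); break
            }
          }
        }
        if (done) break
      }
      if (!done) stop_data("cannot plant missense variant in '%s'",
                           gene_id, class = "introcand_unsatisfiable")
    } else if (eff == "stop_gained") {
      done <- FALSE
      stops <- c("TAA", "TAG", "TGA")
      for (k in cursor:(n_codons - 2)) {
        cod <- codon_at(k)
        if (translate_codon(cod) == "*") next
        for (p in 1:3) {
          if (done) break
          for (b in setdiff(bases, substr(cod, p, p))) {
            new <- cod; substr(new, p, p) <- b
            if (new %in% stops) {
              v <- snp_at_cds((k - 1) * 3 + p, b); done <- TRUE
              cursor <- k + 2L
              add(v$pos, v$ref, v$alt, eff); break
            }
          }
        }
        if (done) break
      }
      if (!done) stop_data("cannot plant stop_gained in '%s'",
                           gene_id, class = "introcand_unsatisfiable")
    } else if (eff == "stop_lost") {
      cod <- codon_at(n_codons)
      if (translate_codon(cod) != "*")
        stop_data("gene '%s' lacks a terminal stop codon", gene_id,
                  class = "introcand_unsatisfiable")
      done <- FALSE
      for (p in 1:3) {
        if (done) break
        for (b in setdiff(bases, substr(cod, p, p))) {
          new <- cod; substr(new, p, p) <- b
          if (translate_codon(new) != "*") {
            v <- snp_at_cds((n_codons - 1) * 3 + p, b); done <- TRUE
            add(v$pos, v$ref, v$alt, eff); break
          }
        }
      }
    } else if (eff == "frameshift_variant") {
      k <- interior_codon()
      cursor <- k + 3L
      p0 <- cds_to_genomic(gm, gene_id, (k - 1) * 3 + 1)
      # 1-bp deletion anchored inside the codon: length change 1 mod 3
      add(p0, substr(s, p0, p0 + 1), substr(s, p0, p0), eff)
    } else if (eff %in% c("conservative_inframe_deletion",
                          "disruptive_inframe_deletion")) {
      off <- if (eff == "conservative_inframe_deletion") 0L else 1L
      k <- interior_codon(off)
      cursor <- k + 3L
      cps <- (k - 1) * 3 + 1:3 + off
      gps <- vapply(cps, function(cp) cds_to_genomic(gm, gene_id, cp),
                    numeric(1))
      lo <- min(gps); hi <- max(gps)
      add(lo - 1L, substr(s, lo - 1L, hi), substr(s, lo - 1L, lo - 1L), eff)
    } else if (eff %in% c("conservative_inframe_insertion",
                          "disruptive_inframe_insertion")) {
      k <- interior_codon()
      cursor <- k + 3L
      cpos <- if (eff == "conservative_inframe_insertion")
        k * 3L else k * 3L + 1L  # codon boundary vs off-boundary
      gp_a <- cds_to_genomic(gm, gene_id, cpos)
      gp_b <- cds_to_genomic(gm, gene_id, cpos + 1L)
      p0 <- min(gp_a, gp_b)
      ins <- "GCT"
      ins_gen <- if (strand == "+") ins else revcomp_chr(ins)
      add(p0, substr(s, p0, p0), paste0(substr(s, p0, p0), ins_gen), eff)
    } else if (eff == "intron_variant") {
      int <- first_intron()
      p0 <- int["start"] + (int["end"] - int["start"]) %/% 2
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "splice_donor_variant") {
      int <- first_intron()
      p0 <- if (strand == "+") int["start"] else int["end"]
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "splice_acceptor_variant") {
      int <- first_intron()
      p0 <- if (strand == "+") int["end"] else int["start"]
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "splice_region_variant") {
      int <- first_intron()
      p0 <- if (strand == "+") int["start"] + 2L else int["end"] - 2L
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "five_prime_UTR_variant") {
      p0 <- if (strand == "+") g$tx_start + 60L else g$tx_end - 60L
      r <- substr(s, p0, p0)
      done <- FALSE
      for (b in setdiff(bases, r)) {
        # avoid creating an upstream ATG (that would be a start-gain call)
        lo <- p0 - 2L; hi <- p0 + 2L
        win <- substr(s, lo, hi)
        altwin <- win; substr(altwin, p0 - lo + 1L, p0 - lo + 1L) <- b
        if (strand == "-") { win <- revcomp_chr(win)
                             altwin <- revcomp_chr(altwin) }
        if (!grepl("ATG", altwin, fixed = TRUE) ||
            grepl("ATG", win, fixed = TRUE)) {
          add(p0, r, b, eff); done <- TRUE; break
        }
      }
      if (!done) stop_data("cannot plant 5'UTR variant in '%s'", gene_id,
                           class = "introcand_unsatisfiable")
    } else if (eff == "three_prime_UTR_variant") {
      p0 <- if (strand == "+") g$tx_end - 60L else g$tx_start + 60L
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "upstream_gene_variant") {
      p0 <- if (strand == "+") g$tx_start - 1000L else g$tx_end + 1000L
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "downstream_gene_variant") {
      p0 <- if (strand == "+") g$tx_end + 1000L else g$tx_start - 1000L
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    } else if (eff == "intergenic_variant") {
      p0 <- g$tx_end + 4L * flank_bp
      r <- substr(s, p0, p0)
      add(p0, r, setdiff(bases, r)[1], eff)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# cds_sequence on a plain character chromosome (fast path for planting).
cds_sequence_chr <- function(gm, gene_id, s) {
  iv <- gene_intervals(gm, gene_id, "cds")
  parts <- vapply(seq_len(nrow(iv)), function(k)
    substr(s, iv[k, "start"], iv[k, "end"]), character(1))
  out <- paste(parts, collapse = "")
  if (gene_row(gm, gene_id)$strand == "-") out <- revcomp_chr(out)
  out
}
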
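#' Effect vocabulary and impact-tier map
#'
#' The fixed mapping from predicted effect terms to impact tiers
#' (HIGH, MODERATE, LOW, MODIFIER), in the style of common variant
#' annotators.
#'
#' @return Named character vector: effect term -> impact tier.
#' @export
effect_impact_map <- function() {
  c(frameshift_variant = "HIGH",
    stop_gained = "HIGH",
    stop_lost = "HIGH",
    splice_donor_variant = "HIGH",
    splice_acceptor_variant = "HIGH",
    bidirectional_gene_fusion = "HIGH",
    missense_variant = "MODERATE",
    conservative_inframe_insertion = "MODERATE",
    conservative_inframe_deletion = "MODERATE",
    disruptive_inframe_insertion = "MODERATE",
    disruptive_inframe_deletion = "MODERATE",
    synonymous_variant = "LOW",
    splice_region_variant = "LOW",
    intergenic_variant = "MODIFIER",
    upstream_gene_variant = "MODIFIER",
    downstream_gene_variant = "MODIFIER",
    intron_variant = "MODIFIER",
    five_prime_UTR_variant = "MODIFIER",
    three_prime_UTR_variant = "MODIFIER",
    five_prime_UTR_premature_start_codon_gain_variant = "MODIFIER")
}

impact_rank <- function(impact) {
  match(impact, c("HIGH", "MODERATE", "LOW", "MODIFIER"))
}

# Translate one codon with the standard nuclear code; "*" is stop.
translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Locate a variant relative to gene models
#'
#' Determines the gene-model context of a position: exon (CDS), UTRs
#' (strand-aware sidedness), intron, splice region (within 3 bp of an
#' exon-intron junction), upstream/downstream flanks (strand-aware,
#' `flank_bp`), or intergenic.  When the position falls inside several
#' genes, one row per gene is returned.
#'
#' @param v single-row variant record (or a list with chrom/pos).
#' @param gm a [gene_models] object.
#' @param flank_bp up/downstream flank distance in bp (default 5000).
#' @return data.frame with gene (NA for intergenic) and region; one row
#'   per overlapping gene, or a single intergenic/flank row.
#' @export
locate_variant <- function(v, gm, flank_bp = 5000) {
  pos <- v$pos
  g <- gm$genes[gm$genes$chrom == v$chrom, , drop = FALSE]
  inside <- g[g$tx_start <= pos & g$tx_end >= pos, , drop = FALSE]
  if (nrow(inside) > 0) {
    rows <- lapply(seq_len(nrow(inside)), function(i) {
      data.frame(gene = inside$gene_id[i],
                 region = region_within_gene(gm, inside$gene_id[i], pos),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  # flanks (strand-aware): upstream is 5' of the transcript
  flank_rows <- list()
  for (i in seq_len(nrow(g))) {
    st <- g$strand[i]
    before <- pos < g$tx_start[i] && pos >= g$tx_start[i] - flank_bp
    after <- pos > g$tx_end[i] && pos <= g$tx_end[i] + flank_bp
    if (before || after) {
      region <- if ((before && st == "+") || (after && st == "-"))
        "upstream" else "downstream"
      flank_rows[[length(flank_rows) + 1L]] <-
        data.frame(gene = g$gene_id[i], region = region,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(flank_rows) > 0) return(do.call(rbind, flank_rows))
  data.frame(gene = NA_character_, region = "intergenic",
             stringsAsFactors = FALSE)
}

# Region of a position known to lie within a gene's transcript span.
region_within_gene <- function(gm, gene_id, pos) {
  grow <- gene_row(gm, gene_id)
  ex <- gene_intervals(gm, gene_id, "exon")
  in_exon <- any(pos >= ex[, "start"] & pos <= ex[, "end"])
  # splice-region override: within 3 bp of an exon-intron junction
  near_junction <- FALSE
  for (k in seq_len(nrow(ex))) {
    if (ex[k, "start"] > grow$tx_start &&
        abs(pos - ex[k, "start"]) <= 3) near_junction <- TRUE
    if (ex[k, "end"] < grow$tx_end &&
        abs(pos - ex[k, "end"]) <= 3) near_junction <- TRUE
  }
  if (!in_exon) {
    return(if (near_junction) "splice_region" else "intron")
  }
  if (near_junction) return("splice_region")
  cds <- gene_intervals(gm, gene_id, "cds")
  if (nrow(cds) > 0 &&
      any(pos >= cds[, "start"] & pos <= cds[, "end"])) return("exon")
  if (nrow(cds) == 0) return("exon")
  cds_lo <- min(cds[, "start"]); cds_hi <- max(cds[, "end"])
  five <- if (grow$strand == "+") pos < cds_lo else pos > cds_hi
  if (five) "five_prime_utr" else "three_prime_utr"
}

# Is an intronic position in the donor (first 2 intron bases, transcript
# orientation) or acceptor (last 2) site?  Returns NULL if neither.
splice_site_effect <- function(gm, gene_id, pos) {
  grow <- gene_row(gm, gene_id)
  ex <- gene_intervals(gm, gene_id, "exon")
  if (nrow(ex) < 2) return(NULL)
  for (k in seq_len(nrow(ex) - 1)) {
    int_start <- ex[k, "end"] + 1L
    int_end <- ex[k + 1, "start"] - 1L
    if (pos < int_start || pos > int_end) next
    at_low <- pos - int_start < 2L   # first two intron bases, genomic
    at_high <- int_end - pos < 2L
    if (grow$strand == "+") {
      if (at_low) return("splice_donor_variant")
      if (at_high) return("splice_acceptor_variant")
    } else {
      if (at_high) return("splice_donor_variant")
      if (at_low) return("splice_acceptor_variant")
    }
  }
  NULL
}

region_modifier_effect <- c(
  intergenic = "intergenic_variant",
  upstream = "upstream_gene_variant",
  downstream = "downstream_gene_variant",
  intron = "intron_variant",
  five_prime_utr = "five_prime_UTR_variant",
  three_prime_utr = "three_prime_UTR_variant")

#' Annotate the protein-level effect of one variant in one gene
#'
#' Classifies a variant against a single gene model and the reference
#' chromosome sequence.  CDS SNPs are translated before/after
#' (strand-aware, standard nuclear code) into synonymous, missense,
#' stop-gained or stop-lost calls; CDS indels become frameshift
#' (length not a multiple of 3) or in-frame insertions/deletions,
#' conservative when the edit aligns on codon boundaries and disruptive
#' otherwise.  Non-CDS contexts map to their region's MODIFIER/LOW/HIGH
#' term (UTR, intron, splice region, splice donor/acceptor,
#' up/downstream).
#'
#' @param v single-row variant record.
#' @param gm a [gene_models] object.
#' @param gene_id gene to annotate against, or `NA` for intergenic.
#' @param chrom_seq `DNAString` of the variant's chromosome (required for
#'   CDS effects).
#' @param region optional precomputed region from [locate_variant()].
#' @param flank_bp flank used when `region` must be computed.
#' @return data.frame row: chrom, pos, ref, alt, vclass, gene, region,
#'   effect, impact.
#' @export
annotate_effect <- function(v, gm, gene_id, chrom_seq = NULL,
                            region = NULL, flank_bp = 5000) {
  mk <- function(gene, region, effect) {
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               vclass = v$vclass, gene = gene, region = region,
               effect = effect, impact = unname(effect_impact_map()[effect]),
               stringsAsFactors = FALSE)
  }
  if (is.na(gene_id)) return(mk(NA_character_, "intergenic",
                                "intergenic_variant"))
  if (is.null(region)) {
    loc <- locate_variant(v, gm, flank_bp)
    loc <- loc[!is.na(loc$gene) & loc$gene == gene_id, , drop = FALSE]
    if (nrow(loc) == 0)
      stop_data("variant %s:%d does not map to gene '%s'",
                v$chrom, v$pos, gene_id)
    region <- loc$region[1]
  }
  if (region %in% c("intron", "splice_region")) {
    ss <- splice_site_effect(gm, gene_id, v$pos)
    if (!is.null(ss)) return(mk(gene_id, "splice_region", ss))
    if (region == "splice_region") {
      # exonic splice-region positions still get their coding effect
      cds <- gene_intervals(gm, gene_id, "cds")
      in_cds <- nrow(cds) > 0 &&
        any(v$pos >= cds[, "start"] & v$pos <= cds[, "end"])
      if (in_cds && !is.null(chrom_seq)) {
        eff <- cds_effect(v, gm, gene_id, chrom_seq)
        return(mk(gene_id, "splice_region", eff))
      }
      return(mk(gene_id, "splice_region", "splice_region_variant"))
    }
    return(mk(gene_id, region, region_modifier_effect[[region]]))
  }
  if (region %in% c("upstream", "downstream", "three_prime_utr")) {
    return(mk(gene_id, region, region_modifier_effect[[region]]))
  }
  if (region == "five_prime_utr") {
    eff <- "five_prime_UTR_variant"
    if (!is.null(chrom_seq) && v$vclass == "SNP" &&
        utr5_gains_start(v, gm, gene_id, chrom_seq)) {
      eff <- "five_prime_UTR_premature_start_codon_gain_variant"
    }
    return(mk(gene_id, "five_prime_utr", eff))
  }
  # region == "exon": inside CDS (UTR handled above)
  if (is.null(chrom_seq))
    stop_data("chromosome sequence required to annotate CDS effects")
  mk(gene_id, "exon", cds_effect(v, gm, gene_id, chrom_seq))
}

# Does a 5'UTR SNP create a new ATG on the coding strand?
utr5_gains_start <- function(v, gm, gene_id, chrom_seq) {
  strand <- gene_row(gm, gene_id)$strand
  lo <- max(1L, v$pos - 2L)
  hi <- min(length(chrom_seq), v$pos + 2L)
  ref_win <- as.character(Biostrings::subseq(chrom_seq, lo, hi))
  alt_win <- ref_win
  substr(alt_win, v$pos - lo + 1L, v$pos - lo + 1L) <- v$alt
  if (strand == "-") {
    ref_win <- revcomp_chr(ref_win)
    alt_win <- revcomp_chr(alt_win)
  }
  grepl("ATG", alt_win, fixed = TRUE) && !grepl("ATG", ref_win, fixed = TRUE)
}

# Coding-sequence effect of a variant known to fall in the CDS.
cds_effect <- function(v, gm, gene_id, chrom_seq) {
  strand <- gene_row(gm, gene_id)$strand
  ref_at <- as.character(Biostrings::subseq(chrom_seq, v$pos,
                                            v$pos + nchar(v$ref) - 1L))
  if (!identical(ref_at, v$ref))
    stop_data("reference mismatch at %s:%d (VCF ref '%s', sequence '%s')",
              v$chrom, v$pos, v$ref, ref_at,
              class = "introcand_ref_mismatch")
  if (v$vclass == "SNP") {
    cdsseq <- cds_sequence(gm, gene_id, chrom_seq)
    cpos <- genomic_to_cds(gm, gene_id, v$pos)
    codon_i <- (cpos - 1L) %/% 3L
    off <- (cpos - 1L) %% 3L + 1L
    codon <- substr(cdsseq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    base <- if (strand == "+") v$alt else revcomp_chr(v$alt)
    new_codon <- codon
    substr(new_codon, off, off) <- base
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(new_codon)
    n_codons <- nchar(cdsseq) %/% 3L
    if (aa_ref == "*" && aa_alt != "*" && codon_i + 1L == n_codons)
      return("stop_lost")
    if (aa_alt == "*" && aa_ref != "*") return("stop_gained")
    if (aa_ref == aa_alt) return("synonymous_variant")
    return("missense_variant")
  }
  # indel
  len_change <- abs(nchar(v$ref) - nchar(v$alt))
  if (len_change %% 3L != 0L) return("frameshift_variant")
  is_del <- nchar(v$ref) > nchar(v$alt)
  if (is_del) {
    del_pos <- (v$pos + nchar(v$alt)):(v$pos + nchar(v$ref) - 1L)
    cpos <- vapply(del_pos, function(p)
      genomic_to_cds(gm, gene_id, p), integer(1))
    if (anyNA(cpos)) return("disruptive_inframe_deletion")
    cmin <- min(cpos); cmax <- max(cpos)
    contiguous <- (cmax - cmin + 1L) == length(cpos)
    if (contiguous && cmin %% 3L == 1L && cmax %% 3L == 0L)
      "conservative_inframe_deletion" else "disruptive_inframe_deletion"
  } else {
    # insertion between pos and pos+1; conservative iff the insertion
    # point sits on a codon boundary in transcript orientation
    c1 <- genomic_to_cds(gm, gene_id, v$pos)
    c2 <- genomic_to_cds(gm, gene_id, v$pos + 1L)
    cl <- suppressWarnings(min(c(c1, c2), na.rm = TRUE))
    if (!is.finite(cl)) return("disruptive_inframe_insertion")
    if (cl %% 3L == 0L) "conservative_inframe_insertion"
    else "disruptive_inframe_insertion"
  }
}

#' Annotate a set of variants against gene models
#'
#' Runs [locate_variant()] and [annotate_effect()] for every record,
#' emitting one annotation per overlapping gene (no most-severe
#' collapsing).  A deletion whose span covers CDS of two genes on
#' opposite strands is reported as a bidirectional gene fusion (HIGH)
#' for both genes.
#'
#' @param records variant-record `data.frame`.
#' @param gm a [gene_models] object.
#' @param genome named `DNAStringSet` of chromosome sequences (optional
#'   but required for CDS effect calls).
#' @param flank_bp up/downstream flank (default 5000).
#' @return data.frame of annotations.
#' @export
annotate_variants <- function(records, gm, genome = NULL, flank_bp = 5000) {
  if (nrow(records) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      vclass = character(), gene = character(),
                      region = character(), effect = character(),
                      impact = character(), stringsAsFactors = FALSE))
  }
  # fast path: variants farther than flank_bp from every gene are
  # intergenic and need no per-gene logic
  g <- gm$genes
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$tx_start - flank_bp),
                              g$tx_end + flank_bp))
  gr_var <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(records$pos, records$pos))
  near <- rep(FALSE, nrow(records))
  shared <- records$chrom %in% g$chrom
  if (any(shared)) {
    hits <- GenomicRanges::findOverlaps(gr_var, gr_gene)
    near[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  inter <- records[!near, , drop = FALSE]
  inter_ann <- if (nrow(inter) > 0) {
    data.frame(chrom = inter$chrom, pos = inter$pos, ref = inter$ref,
               alt = inter$alt, vclass = inter$vclass,
               gene = NA_character_, region = "intergenic",
               effect = "intergenic_variant", impact = "MODIFIER",
               stringsAsFactors = FALSE)
  } else NULL
  slow <- which(near)
  out <- vector("list", length(slow))
  for (oi in seq_along(slow)) {
    i <- slow[oi]
    v <- records[i, ]
    chrom_seq <- if (!is.null(genome) && v$chrom %in% names(genome))
      genome[[v$chrom]] else NULL
    loc <- locate_variant(v, gm, flank_bp)
    fusion_genes <- deletion_fusion_genes(v, gm)
    loc <- loc[is.na(loc$gene) | !loc$gene %in% fusion_genes, ,
               drop = FALSE]
    rows <- lapply(seq_len(nrow(loc)), function(k) {
      annotate_effect(v, gm, loc$gene[k], chrom_seq,
                      region = loc$region[k], flank_bp = flank_bp)
    })
    if (length(fusion_genes) > 0) {
      rows <- c(rows, lapply(fusion_genes, function(gid) {
        data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                   vclass = v$vclass, gene = gid, region = "exon",
                   effect = "bidirectional_gene_fusion", impact = "HIGH",
                   stringsAsFactors = FALSE)
      }))
    }
    out[[oi]] <- do.call(rbind, rows)
  }
  res <- rbind(inter_ann, do.call(rbind, out))
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Genes fused by a deletion spanning CDS of two opposite-strand genes.
deletion_fusion_genes <- function(v, gm) {
  if (v$vclass != "InDel" || nchar(v$ref) <= nchar(v$alt)) return(character())
  span <- c(v$pos + nchar(v$alt), v$pos + nchar(v$ref) - 1L)
  g <- gm$genes[gm$genes$chrom == v$chrom, , drop = FALSE]
  hit <- character()
  for (i in seq_len(nrow(g))) {
    cds <- gene_intervals(gm, g$gene_id[i], "cds")
    if (nrow(cds) == 0) next
    if (any(cds[, "start"] <= span[2] & cds[, "end"] >= span[1]))
      hit <- c(hit, g$gene_id[i])
  }
  if (length(hit) >= 2 &&
      length(unique(g$strand[match(hit, g$gene_id)])) == 2) hit
  else character()
}

#' Summarize annotations by impact tier and effect term
#'
#' When a variant carries several annotations (one per overlapping
#' gene), only its most severe impact is counted, matching per-variant
#' reporting conventions.  Percentages are computed to one decimal.
#'
#' @param ann annotation data.frame from [annotate_variants()].
#' @return list with `by_impact` (impact, n, percent) and `by_effect`
#'   (effect, n) data.frames, and `n_variants`.
#' @export
summarize_impacts <- function(ann) {
  tiers <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (nrow(ann) == 0) {
    return(list(by_impact = data.frame(impact = tiers, n = 0L, percent = 0),
                by_effect = data.frame(effect = character(), n = integer()),
                n_variants = 0L))
  }
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  best <- tapply(impact_rank(ann$impact), key, min)
  n_var <- length(best)
  counts <- vapply(seq_along(tiers), function(r) sum(best == r), integer(1))
  by_impact <- data.frame(impact = tiers, n = counts,
                          percent = round(100 * counts / n_var, 1))
  # per-variant most severe effect (first effect at the best tier)
  sel <- !duplicated(key)
  ord <- order(key, impact_rank(ann$impact))
  ann_o <- ann[ord, ]
  first <- ann_o[!duplicated(paste(ann_o$chrom, ann_o$pos, ann_o$ref,
                                   ann_o$alt, sep = ":")), ]
  eff_tab <- table(first$effect)
  by_effect <- data.frame(effect = names(eff_tab),
                          n = as.integer(eff_tab),
                          stringsAsFactors = FALSE)
  list(by_impact = by_impact, by_effect = by_effect, n_variants = n_var)
}

#' Write annotations as TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(ann, path) write_tsv_plain(ann, path)

#' Write annotated variants as a VCF with an `ANN` INFO tag
#'
#' One VCF record per variant; annotations for all overlapping genes are
#' joined with commas in `ANN=gene|region|effect|impact` format.
#'
#' @param ann annotation data.frame from [annotate_variants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations_vcf <- function(ann, path) {
  hdr <- c("##fileformat=VCFv4.2", "##source=introcand",
           paste0("##INFO=<ID=ANN,Number=.,Type=String,",
                  "Description=\"Effect annotation: ",
                  "gene|region|effect|impact\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = "\r")
  tag <- paste(ifelse(is.na(ann$gene), "", ann$gene), ann$region,
               ann$effect, ann$impact, sep = "|")
  by_var <- tapply(tag, key, paste, collapse = ",")
  first <- ann[!duplicated(key), ]
  ord <- order(first$chrom, first$pos)
  first <- first[ord, ]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tANN=%s",
                  first$chrom, first$pos, first$ref, first$alt,
                  unname(by_var[paste(first$chrom, first$pos, first$ref,
                                      first$alt, sep = "\r")]))
  writeLines(c(hdr, body), path)
  invisible(path)
}
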
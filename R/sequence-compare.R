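#' Classify focal variants as shared with a donor or private
#'
#' A focal variant is shared iff an identical `(chrom, pos, ref, alt)`
#' key exists in the donor call set (both sets must be called against
#' the same reference build); otherwise it is private.  A donor record
#' at the same position with a different REF allele indicates a
#' coordinate-system mismatch and is flagged.
#'
#' @param focal variant-record `data.frame` for the focal genotype.
#' @param donor variant-record `data.frame` (or any data.frame with
#'   chrom, pos, ref, alt) for the donor.
#' @return `focal` with added columns `status` (`shared`/`private`) and
#'   `ref_mismatch` (logical).
#' @export
classify_variant_sharing <- function(focal, donor) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  poskey <- function(df) paste(df$chrom, df$pos, sep = ":")
  refkey <- function(df) paste(df$chrom, df$pos, df$ref, sep = ":")
  out <- focal
  out$status <- ifelse(key(focal) %in% key(donor), "shared", "private")
  same_pos <- poskey(focal) %in% poskey(donor)
  same_ref <- refkey(focal) %in% refkey(donor)
  out$ref_mismatch <- same_pos & !same_ref
  if (any(out$ref_mismatch))
    warning(sprintf("%d position(s) with disagreeing REF alleles; %s",
                    sum(out$ref_mismatch),
                    "check that both call sets use the same reference"))
  out
}

#' Percent identity between two sequences
#'
#' Global Needleman-Wunsch alignment with affine gap costs
#' (defaults: match 1, mismatch -1, gap open -2, gap extend -1);
#' identity is the number of identical aligned columns divided by the
#' total number of alignment columns (gaps included), as a percentage to
#' two decimals.
#'
#' @param seqA,seqB sequences (`DNAString` or character), non-empty.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return Numeric percentage in `[0, 100]`.
#' @export
percent_identity <- function(seqA, seqB, match = 1, mismatch = -1,
                             gap_open = -2, gap_extend = -1) {
  a <- if (is.character(seqA)) seqA else as.character(seqA)
  b <- if (is.character(seqB)) seqB else as.character(seqB)
  if (!nzchar(a) || !nzchar(b)) stop_data("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  ca <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  round(100 * sum(ca == cb & ca != "-") / length(ca), 2)
}

#' Alignment score of the global alignment used by [percent_identity()]
#'
#' Exposed for validation against independent dynamic-programming
#' implementations.
#'
#' @inheritParams percent_identity
#' @return Numeric alignment score.
#' @export
alignment_score <- function(seqA, seqB, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  a <- if (is.character(seqA)) seqA else as.character(seqA)
  b <- if (is.character(seqB)) seqB else as.character(seqB)
  if (!nzchar(a) || !nzchar(b)) stop_data("empty sequence")
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    scoreOnly = TRUE)
}

#' Per-gene sharing report against a donor genotype
#'
#' For each gene, counts shared vs private HIGH/MODERATE variants and
#' computes percent identity of the focal gene sequence against the
#' donor gene sequence (both reconstructed by applying the respective
#' call sets to the reference).
#'
#' @param gene_ids genes to report.
#' @param gm a [gene_models] object.
#' @param genome named `DNAStringSet` reference.
#' @param focal,donor variant-record data.frames.
#' @param annotations annotation data.frame (to restrict the counts to
#'   HIGH/MODERATE variants); `NULL` counts all variants in the gene.
#' @return data.frame with gene_id, shared_n, private_n,
#'   identity_vs_donor, fully_donor.
#' @export
sharing_report <- function(gene_ids, gm, genome, focal, donor,
                           annotations = NULL) {
  rows <- lapply(gene_ids, function(id) {
    g <- gene_row(gm, id)
    span <- c(g$tx_start, g$tx_end)
    fv <- focal[focal$chrom == g$chrom & focal$pos >= span[1] &
                  focal$pos <= span[2], , drop = FALSE]
    fv_sev <- fv
    if (!is.null(annotations)) {
      sev <- annotations[!is.na(annotations$gene) & annotations$gene == id &
                           annotations$impact %in% c("HIGH", "MODERATE"), ]
      keep <- paste(fv$chrom, fv$pos, fv$ref, fv$alt) %in%
        paste(sev$chrom, sev$pos, sev$ref, sev$alt)
      fv_sev <- fv[keep, , drop = FALSE]
    }
    cls <- classify_variant_sharing(fv_sev, donor)
    chrom_seq <- genome[[g$chrom]]
    ref_gene <- Biostrings::subseq(chrom_seq, span[1], span[2])
    dv <- donor[donor$chrom == g$chrom & donor$pos >= span[1] &
                  donor$pos <= span[2], , drop = FALSE]
    foc_seq <- apply_variants(ref_gene, fv, offset = span[1] - 1L)
    don_seq <- apply_variants(ref_gene, dv, offset = span[1] - 1L)
    idy <- percent_identity(foc_seq, don_seq)
    data.frame(gene_id = id,
               shared_n = sum(cls$status == "shared"),
               private_n = sum(cls$status == "private"),
               identity_vs_donor = idy,
               fully_donor = idy == 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply variant calls to a reference sequence
#'
#' Substitutes/inserts/deletes the given alleles into a reference
#' (sub)sequence, processing positions in descending order so earlier
#' coordinates stay valid.  Variants whose REF allele does not match the
#' sequence are rejected.
#'
#' @param seq `DNAString` (sub)sequence.
#' @param variants variant-record rows falling inside the sequence.
#' @param offset genomic coordinate of `seq` position 1, minus 1.
#' @return A `DNAString` with the variants applied.
#' @export
apply_variants <- function(seq, variants, offset = 0L) {
  s <- as.character(seq)
  if (nrow(variants) == 0) return(Biostrings::DNAString(s))
  v <- variants[order(-variants$pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i] - offset
    w <- nchar(v$ref[i])
    if (p < 1 || p + w - 1L > nchar(s)) next  # allele extends outside
    if (substr(s, p, p + w - 1L) != v$ref[i])
      stop_data("reference mismatch applying %s:%d %s>%s",
                v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                class = "introcand_ref_mismatch")
    s <- paste0(substr(s, 1, p - 1L), v$alt[i],
                substr(s, p + w, nchar(s)))
  }
  Biostrings::DNAString(s)
}
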
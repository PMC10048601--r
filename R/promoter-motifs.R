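#' Load a cis-element motif catalog
#'
#' Reads a TSV catalog of named IUPAC consensus strings (columns: name,
#' consensus, category).  The packaged default catalog transcribes the
#' common plant cis-regulatory elements (ARE, ABRE, HSE, CGTCA/TGACG,
#' DRE, LTR, MBS, TC-rich repeats, WUN, TCA, GARE, P-box, TATC-box,
#' CCAAT-box, plus light-responsive elements); consensus strings are
#' configuration data and can be edited freely.
#'
#' @param path catalog TSV; default is the packaged catalog.
#' @return data.frame with name, consensus, category.
#' @export
read_motif_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_element_catalog.tsv",
                        package = "introcand", mustWork = TRUE)
  }
  cat <- read_tsv_plain(path)
  stopifnot(all(c("name", "consensus", "category") %in% names(cat)))
  if (anyDuplicated(cat$name))
    stop_data("motif names must be unique", class = "introcand_catalog_error")
  ok <- vapply(cat$consensus, is_iupac, logical(1))
  if (!all(ok))
    stop_data("non-IUPAC consensus for motif(s): %s",
              paste(cat$name[!ok], collapse = ", "),
              class = "introcand_catalog_error")
  cat$consensus <- toupper(cat$consensus)
  cat
}

#' Extract a gene's promoter sequence
#'
#' Strand-aware: for `+` genes the `length_bp` bases ending 1 bp before
#' the gene start; for `-` genes the reverse complement of the bases
#' starting 1 bp after the gene end.  Truncated with a warning at
#' chromosome edges.  "Gene start" is the transcript start by default;
#' `from = "cds"` switches to the translation start.
#'
#' @param gm a [gene_models] object.
#' @param gene_id gene id.
#' @param genome named `DNAStringSet`.
#' @param length_bp promoter length (default 3000).
#' @param from `"tx"` (transcript start, default) or `"cds"`.
#' @return A `DNAString` promoter sequence (5' to 3' on the coding
#'   strand).
#' @export
extract_promoter <- function(gm, gene_id, genome, length_bp = 3000,
                             from = c("tx", "cds")) {
  from <- match.arg(from)
  g <- gene_row(gm, gene_id)
  if (!g$chrom %in% names(genome))
    stop_data("chromosome '%s' absent from genome", g$chrom)
  chrom_seq <- genome[[g$chrom]]
  L <- length(chrom_seq)
  anchor <- if (from == "tx") {
    if (g$strand == "+") g$tx_start else g$tx_end
  } else {
    cds <- gene_intervals(gm, gene_id, "cds")
    if (nrow(cds) == 0) stop_data("gene '%s' has no CDS", gene_id)
    if (g$strand == "+") min(cds[, "start"]) else max(cds[, "end"])
  }
  if (g$strand == "+") {
    lo <- anchor - length_bp
    hi <- anchor - 1L
    if (lo < 1L) {
      warning(sprintf("promoter of %s truncated at chromosome start (%d bp)",
                      gene_id, max(hi, 0L)))
      lo <- 1L
    }
    if (hi < 1L) return(Biostrings::DNAString(""))
    Biostrings::subseq(chrom_seq, lo, hi)
  } else {
    lo <- anchor + 1L
    hi <- anchor + length_bp
    if (hi > L) {
      warning(sprintf("promoter of %s truncated at chromosome end (%d bp)",
                      gene_id, max(L - lo + 1L, 0L)))
      hi <- L
    }
    if (lo > L) return(Biostrings::DNAString(""))
    Biostrings::reverseComplement(Biostrings::subseq(chrom_seq, lo, hi))
  }
}

#' Scan a sequence against a motif catalog
#'
#' Reports every position where a consensus matches under IUPAC
#' semantics (ambiguity codes expanded in the consensus only, so an `N`
#' in the sequence never matches a non-N consensus symbol).  Overlapping
#' hits are allowed.  Reverse-strand hits are matches of the
#' reverse-complemented consensus, reported at their start offset on the
#' given sequence.
#'
#' @param seq `DNAString` or character sequence over A/C/G/T/N.
#' @param catalog motif catalog data.frame (see [read_motif_catalog()]).
#' @param both_strands scan both strands (default `TRUE`).
#' @return data.frame with motif, offset (1-based), strand, match.
#' @export
scan_motifs <- function(seq, catalog, both_strands = TRUE) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  ok <- vapply(catalog$consensus, is_iupac, logical(1))
  if (!all(ok))
    stop_data("non-IUPAC consensus for motif(s): %s",
              paste(catalog$name[!ok], collapse = ", "),
              class = "introcand_catalog_error")
  out <- list()
  scan_one <- function(consensus, name, strand) {
    pat <- Biostrings::DNAString(consensus)
    if (length(pat) > length(seq)) return(NULL)
    m <- Biostrings::matchPattern(pat, seq, fixed = "subject")
    if (length(m) == 0) return(NULL)
    data.frame(motif = name,
               offset = Biostrings::start(m),
               strand = strand,
               match = as.character(m),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(catalog))) {
    out[[length(out) + 1L]] <-
      scan_one(catalog$consensus[i], catalog$name[i], "+")
    if (both_strands) {
      rc <- revcomp_chr(catalog$consensus[i])
      out[[length(out) + 1L]] <- scan_one(rc, catalog$name[i], "-")
    }
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    return(data.frame(motif = character(), offset = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$motif, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Export promoter sequences as FASTA
#'
#' Extracts the promoters of the given genes (see [extract_promoter()])
#' and writes them to a FASTA file named by gene id.
#'
#' @param gm a [gene_models] object.
#' @param gene_ids genes to export.
#' @param genome named `DNAStringSet`.
#' @param path output FASTA path.
#' @param length_bp promoter length (default 3000).
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(gm, gene_ids, genome, path,
                                 length_bp = 3000) {
  seqs <- Biostrings::DNAStringSet(vapply(gene_ids, function(id)
    as.character(extract_promoter(gm, id, genome, length_bp)),
    character(1)))
  names(seqs) <- gene_ids
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Compare two genotypes' promoters for mutated cis elements
#'
#' Aligns the two promoter sequences (end-gap-free global alignment,
#' match 1 / mismatch -1 / gap -2), scans both against the catalog, and
#' calls a motif hit "mutated" when its footprint covers at least one
#' aligned column where the sequences differ, or when the hit exists in
#' only one of the two sequences.  Also flags whether a heat shock
#' element (HSE) consensus is present in either promoter.
#'
#' @param seqA,seqB promoter sequences (`DNAString` or character);
#'   typically reference vs focal genotype.
#' @param catalog motif catalog data.frame.
#' @return list with `per_motif` (motif, count_a, count_b, mutated_n),
#'   `mutated_total`, `hse_present_a`, `hse_present_b`.
#' @export
compare_promoters <- function(seqA, seqB, catalog) {
  a <- if (is.character(seqA)) seqA else as.character(seqA)
  b <- if (is.character(seqB)) seqB else as.character(seqB)
  if (!nzchar(a) || !nzchar(b)) stop_data("empty promoter sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  # rebuild full alignment columns: the overlap alignment clips
  # unaligned ends, which we reinstate as end-gap columns
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  qs <- Biostrings::start(Biostrings::subject(aln))
  qe <- Biostrings::end(Biostrings::subject(aln))
  pre_a <- substr(a, 1, ps - 1); suf_a <- substr(a, pe + 1, nchar(a))
  pre_b <- substr(b, 1, qs - 1); suf_b <- substr(b, qe + 1, nchar(b))
  aln_a <- as.character(Biostrings::alignedPattern(aln))
  aln_b <- as.character(Biostrings::alignedSubject(aln))
  gaps <- function(n) strrep("-", n)
  full_a <- paste0(pre_a, gaps(nchar(pre_b)), aln_a,
                   suf_a, gaps(nchar(suf_b)))
  full_b <- paste0(gaps(nchar(pre_a)), pre_b, aln_b,
                   gaps(nchar(suf_a)), suf_b)
  ca <- strsplit(full_a, "")[[1]]
  cb <- strsplit(full_b, "")[[1]]
  differs <- ca != cb  # gap vs base counts as a difference
  col_a <- which(ca != "-")  # col_a[p] = alignment column of A position p
  col_b <- which(cb != "-")
  hits_a <- scan_motifs(a, catalog)
  hits_b <- scan_motifs(b, catalog)
  width <- nchar(catalog$consensus)[match(hits_a$motif, catalog$name)]
  width_b <- nchar(catalog$consensus)[match(hits_b$motif, catalog$name)]

  key_of <- function(hits, cols, widths) {
    if (nrow(hits) == 0) return(character())
    start_col <- cols[hits$offset]
    paste(hits$motif, start_col, hits$strand, sep = "|")
  }
  foot_mutated <- function(hits, cols, widths) {
    if (nrow(hits) == 0) return(logical())
    vapply(seq_len(nrow(hits)), function(i) {
      span <- cols[hits$offset[i]:min(hits$offset[i] + widths[i] - 1L,
                                      length(cols))]
      any(differs[span])
    }, logical(1))
  }
  ka <- key_of(hits_a, col_a, width)
  kb <- key_of(hits_b, col_b, width_b)
  ma <- foot_mutated(hits_a, col_a, width)
  mb <- foot_mutated(hits_b, col_b, width_b)
  all_keys <- union(ka, kb)
  mutated_key <- vapply(all_keys, function(k) {
    in_a <- k %in% ka
    in_b <- k %in% kb
    if (xor(in_a, in_b)) return(TRUE)
    any(ma[ka == k]) || any(mb[kb == k])
  }, logical(1))
  motif_of_key <- sub("\\|.*$", "", all_keys)
  motifs <- sort(unique(c(hits_a$motif, hits_b$motif)))
  per_motif <- data.frame(
    motif = motifs,
    count_a = vapply(motifs, function(m) sum(hits_a$motif == m), integer(1)),
    count_b = vapply(motifs, function(m) sum(hits_b$motif == m), integer(1)),
    mutated_n = vapply(motifs, function(m)
      sum(mutated_key[motif_of_key == m]), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_motif) <- NULL
  hse_names <- catalog$name[grepl("HSE", catalog$name, ignore.case = TRUE)]
  list(per_motif = per_motif,
       mutated_total = sum(mutated_key),
       hse_present_a = any(hits_a$motif %in% hse_names),
       hse_present_b = any(hits_b$motif %in% hse_names))
}
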
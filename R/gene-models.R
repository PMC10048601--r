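#' Gene model container
#'
#' A lightweight container for gene models: a `genes` table
#' (gene_id, chrom, strand, tx_start, tx_end, description) and a `features`
#' table of exon and CDS intervals (gene_id, type, start, end), all 1-based
#' inclusive genomic coordinates.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tx_start`, `tx_end`, `description`.
#' @param features data.frame with columns `gene_id`, `type`
#'   (`"exon"` or `"cds"`), `start`, `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, features) {
  stopifnot(is.data.frame(genes), is.data.frame(features))
  need_g <- c("gene_id", "chrom", "strand", "tx_start", "tx_end", "description")
  need_f <- c("gene_id", "type", "start", "end")
  if (!all(need_g %in% names(genes)))
    stop_data("gene table missing columns: %s",
              paste(setdiff(need_g, names(genes)), collapse = ", "))
  if (!all(need_f %in% names(features)))
    stop_data("feature table missing columns: %s",
              paste(setdiff(need_f, names(features)), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop_data("strand must be '+' or '-'")
  features <- features[order(features$gene_id, features$type, features$start), ]
  obj <- list(genes = genes, features = features)
  class(obj) <- "gene_models"
  obj
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

# Sorted interval matrix (start, end) for one gene and feature type.
gene_intervals <- function(gm, gene_id, type = c("cds", "exon")) {
  type <- match.arg(type)
  f <- gm$features
  f <- f[f$gene_id == gene_id & f$type == type, , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  cbind(start = f$start, end = f$end)
}

gene_row <- function(gm, gene_id) {
  i <- match(gene_id, gm$genes$gene_id)
  if (is.na(i)) stop_data("unknown gene id '%s'", gene_id)
  gm$genes[i, , drop = FALSE]
}

# Total CDS length in bp.
cds_length <- function(gm, gene_id) {
  iv <- gene_intervals(gm, gene_id, "cds")
  if (nrow(iv) == 0) 0L else sum(iv[, "end"] - iv[, "start"] + 1L)
}

# Map a genomic position (inside a CDS interval) to a 1-based coordinate
# along the spliced CDS in *transcript orientation*.  NA if not in CDS.
genomic_to_cds <- function(gm, gene_id, pos) {
  iv <- gene_intervals(gm, gene_id, "cds")
  if (nrow(iv) == 0) return(NA_integer_)
  total <- sum(iv[, "end"] - iv[, "start"] + 1L)
  fwd <- NA_integer_
  acc <- 0L
  for (k in seq_len(nrow(iv))) {
    if (pos >= iv[k, "start"] && pos <= iv[k, "end"]) {
      fwd <- acc + (pos - iv[k, "start"] + 1L)
      break
    }
    acc <- acc + (iv[k, "end"] - iv[k, "start"] + 1L)
  }
  if (is.na(fwd)) return(NA_integer_)
  if (gene_row(gm, gene_id)$strand == "+") fwd else total - fwd + 1L
}

# Spliced CDS sequence in transcript orientation (character string).
cds_sequence <- function(gm, gene_id, chrom_seq) {
  iv <- gene_intervals(gm, gene_id, "cds")
  if (nrow(iv) == 0) return("")
  parts <- vapply(seq_len(nrow(iv)), function(k) {
    as.character(Biostrings::subseq(chrom_seq, iv[k, "start"], iv[k, "end"]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gene_row(gm, gene_id)$strand == "-") s <- revcomp_chr(s)
  s
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features; the free-text functional
#' annotation is stored in a `description=` attribute on the gene line.
#'
#' @param gm a [gene_models] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gm, path) {
  enc <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))
  lines <- "##gff-version 3"
  g <- gm$genes[order(gm$genes$chrom, gm$genes$tx_start), ]
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    lines <- c(lines,
      sprintf("%s\tintrocand\tgene\t%d\t%d\t.\t%s\t.\tID=%s;description=%s",
              g$chrom[i], g$tx_start[i], g$tx_end[i], g$strand[i],
              id, enc(g$description[i])),
      sprintf("%s\tintrocand\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chrom[i], g$tx_start[i], g$tx_end[i], g$strand[i], id, id))
    ex <- gene_intervals(gm, id, "exon")
    for (k in seq_len(nrow(ex))) {
      lines <- c(lines,
        sprintf("%s\tintrocand\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
                g$chrom[i], ex[k, "start"], ex[k, "end"], g$strand[i], id))
    }
    cds <- gene_intervals(gm, id, "cds")
    # phase: bases to skip to reach the next codon start, in transcript order
    lens <- cds[, "end"] - cds[, "start"] + 1L
    ord <- if (g$strand[i] == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    phase <- integer(nrow(cds))
    acc <- 0L
    for (k in ord) {
      phase[k] <- (3L - (acc %% 3L)) %% 3L
      acc <- acc + lens[k]
    }
    for (k in seq_len(nrow(cds))) {
      lines <- c(lines,
        sprintf("%s\tintrocand\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.1",
                g$chrom[i], cds[k, "start"], cds[k, "end"], g$strand[i],
                phase[k], id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Expects the layout written by [write_gene_models_gff3()]: gene features
#' carrying `ID` and `description` attributes, with exon and CDS children.
#'
#' @param path GFF3 file path.
#' @return A [gene_models] object.
#' @export
read_gene_models_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (length(raw) == 0) stop_data("no features in GFF3 file '%s'", path)
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad) > 0)
    stop_data("malformed GFF3 line %d in '%s'", bad[1], path)
  m <- do.call(rbind, parts)
  attr_get <- function(attrs, key) {
    hit <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
    out <- rep(NA_character_, length(attrs))
    ok <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)", key, "="), attrs))) > 0
    val <- sub(paste0("^;?", key, "="), "", hit)
    out[ok] <- gsub("%3B", ";", gsub("%3D", "=", val))
    out
  }
  type <- m[, 3]
  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = attr_get(m[is_gene, 9], "ID"),
    chrom = m[is_gene, 1],
    strand = m[is_gene, 7],
    tx_start = as.integer(m[is_gene, 4]),
    tx_end = as.integer(m[is_gene, 5]),
    description = attr_get(m[is_gene, 9], "description"),
    stringsAsFactors = FALSE)
  child <- type %in% c("exon", "CDS")
  parent <- sub("\\.1$", "", attr_get(m[child, 9], "Parent"))
  features <- data.frame(
    gene_id = parent,
    type = ifelse(m[child, 3] == "CDS", "cds", "exon"),
    start = as.integer(m[child, 4]),
    end = as.integer(m[child, 5]),
    stringsAsFactors = FALSE)
  gene_models(genes, features)
}
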
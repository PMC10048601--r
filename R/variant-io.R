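#' Construct a variant record table
#'
#' The package-wide variant representation: one row per ALT allele with
#' columns `chrom`, `pos` (1-based), `ref`, `alt`, `qual`, `depth`,
#' `genotype` (`hom_ref`, `het`, `hom_alt`, `missing`) and `vclass`
#' (`SNP` or `InDel`).  `vclass` is always derived from the alleles:
#' a variant is a SNP iff both alleles have length 1.
#'
#' @param chrom,pos,ref,alt,qual,depth,genotype column vectors (recycled
#'   where length 1).
#' @return A `data.frame` of variant records.
#' @export
variant_records <- function(chrom, pos, ref, alt, qual = NA_real_,
                            depth = NA_real_, genotype = "hom_alt") {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   pos = rep_len(as.integer(pos), n),
                   ref = rep_len(toupper(as.character(ref)), n),
                   alt = rep_len(toupper(as.character(alt)), n),
                   qual = rep_len(as.numeric(qual), n),
                   depth = rep_len(as.numeric(depth), n),
                   genotype = rep_len(as.character(genotype), n),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1L)) stop_data("variant pos must be >= 1")
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)))
    stop_data("ref and alt alleles must be non-empty")
  if (any(df$ref == df$alt)) stop_data("ref and alt alleles must differ")
  if (any(!df$genotype %in% c("hom_ref", "het", "hom_alt", "missing")))
    stop_data("genotype must be one of hom_ref, het, hom_alt, missing")
  df$vclass <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L,
                      "SNP", "InDel")
  df
}

#' Variant filtering configuration
#'
#' Thresholds for the quality filtering step: minimum site quality
#' (`minQ`-style), minimum mean depth of coverage, whether to keep only
#' homozygous-alternate calls, and the maximum per-site missing-genotype
#' fraction used when filtering multi-sample panels.  All thresholds are
#' inclusive (`>=`).
#'
#' @param min_qual minimum phred-scaled site quality (default 15).
#' @param min_mean_depth minimum mean read depth (default 15).
#' @param homozygous_alt_only keep only `hom_alt` calls (default `TRUE`).
#' @param max_missing maximum missing fraction for panel sites, in
#'   `[0, 1]` (default 0.5).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_qual = 15, min_mean_depth = 15,
                          homozygous_alt_only = TRUE, max_missing = 0.5) {
  if (min_qual < 0 || min_mean_depth < 0)
    stop_config("filter thresholds must be >= 0 (min_qual, min_mean_depth)")
  if (max_missing < 0 || max_missing > 1)
    stop_config("max_missing must lie in [0, 1]")
  structure(list(min_qual = min_qual, min_mean_depth = min_mean_depth,
                 homozygous_alt_only = isTRUE(homozygous_alt_only),
                 max_missing = max_missing),
            class = "filter_config")
}

# Map a GT string and ALT index to the package genotype vocabulary.
gt_to_genotype <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a)) return("missing")
  n_alt <- sum(a == alt_index)
  if (n_alt == length(a) && length(a) > 0) "hom_alt"
  else if (n_alt > 0) "het"
  else if (all(a == 0)) "hom_ref"
  else "hom_ref"  # homozygous for a different ALT allele of the same site
}

#' Read variants from a VCF file
#'
#' Parses a VCF v4.x file into the package's variant-record table.
#' Multi-allelic sites are split into one record per ALT allele.  The
#' genotype column reflects the first sample's call (for multi-sample
#' panels use [read_genotype_matrix()]).  Missing QUAL or depth values
#' become `NA`, which fails any positive filtering threshold.
#'
#' @param path VCF file path (plain text or bgzip, as supported by vcfR).
#' @return A variant-record `data.frame` (see [variant_records()]).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop_data("VCF file '%s' not found", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^##fileformat=VCF", first))
    stop_data("parse error at line 1 of '%s': missing ##fileformat=VCF header",
              path, class = "introcand_parse_error")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(variant_records(character(), integer(), character(), character())[0, ])
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info_dp <- suppressWarnings(as.numeric(
    vcfR::extract.info(vcf, element = "DP")))
  gt_dp <- NULL
  gt <- NULL
  if (ncol(vcf@gt) >= 2) {
    gtm <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gtm[, 1]
    dpm <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                             as.numeric = TRUE))
    if (!is.null(dpm)) gt_dp <- rowMeans(dpm, na.rm = TRUE)
  }
  depth <- info_dp
  if (!is.null(gt_dp)) depth <- ifelse(is.na(depth), gt_dp, depth)
  depth[is.nan(depth)] <- NA_real_

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    geno <- vapply(seq_along(alts), function(k) {
      if (is.null(gt)) "hom_alt" else gt_to_genotype(gt[i], k)
    }, character(1))
    out[[i]] <- variant_records(chrom = fix[i, "CHROM"],
                                pos = as.integer(fix[i, "POS"]),
                                ref = fix[i, "REF"], alt = alts,
                                qual = qual[i], depth = depth[i],
                                genotype = geno)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter variant records on quality, depth and genotype
#'
#' Keeps exactly the records with `qual >= min_qual`, `depth >=
#' min_mean_depth` and, when `homozygous_alt_only` is set, genotype
#' `hom_alt`.  Missing (`NA`) quality or depth fails any positive
#' threshold.  Record order is preserved and the input is not modified.
#'
#' @param records variant-record `data.frame`.
#' @param cfg a [filter_config()].
#' @return The kept subset of `records`.
#' @export
filter_variants <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(records) == 0) return(records)
  pass_q <- if (cfg$min_qual > 0) {
    !is.na(records$qual) & records$qual >= cfg$min_qual
  } else is.na(records$qual) | records$qual >= cfg$min_qual
  pass_d <- if (cfg$min_mean_depth > 0) {
    !is.na(records$depth) & records$depth >= cfg$min_mean_depth
  } else is.na(records$depth) | records$depth >= cfg$min_mean_depth
  keep <- pass_q & pass_d
  if (cfg$homozygous_alt_only) keep <- keep & records$genotype == "hom_alt"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export variant records as TSV
#'
#' Writes the five columns consumed by downstream modules:
#' chrom, pos, ref, alt, vclass.
#'
#' @param records variant-record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(records, path) {
  write_tsv_plain(records[, c("chrom", "pos", "ref", "alt", "vclass")], path)
}

#' Write variant records as a single-sample VCF v4.2 file
#'
#' @param records variant-record `data.frame`.
#' @param path output path.
#' @param sample_name sample column name.
#' @param contig_lengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(records, path, sample_name = "sample",
                               contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=introcand")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Mean read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  r <- records[order(records$chrom, records$pos), , drop = FALSE]
  qual <- ifelse(is.na(r$qual), ".", sprintf("%.1f", r$qual))
  dp <- ifelse(is.na(r$depth), ".", sprintf("%.1f", r$depth))
  dpi <- ifelse(is.na(r$depth), ".", sprintf("%d", as.integer(round(r$depth))))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%s\tGT:GQ:DP\t%s:99:%s",
                  r$chrom, r$pos, r$ref, r$alt, qual, dp,
                  gt_code[r$genotype], dpi)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a genotype dosage matrix
#'
#' Builds the sample-by-site alternate-allele dosage matrix used for
#' genotype-concordance distances.  Sites are filtered on quality and on
#' missing-genotype fraction (`max_missing`), mirroring the merged-panel
#' filtering step of the phylogenetic analysis.
#'
#' @param path multi-sample VCF path.
#' @param cfg a [filter_config()]; `min_qual` and `max_missing` are used.
#' @return A list with `dosage` (samples x sites integer matrix, values
#'   0/1/2 or `NA`), and `sites` (data.frame chrom, pos, ref, alt).
#' @export
read_genotype_matrix <- function(path, cfg = filter_config()) {
  first <- readLines(path, n = 1L)
  if (!grepl("^##fileformat=VCF", first))
    stop_data("parse error at line 1 of '%s': missing VCF header", path,
              class = "introcand_parse_error")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gtm <- vcfR::extract.gt(vcf, element = "GT")
  dose <- function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a) > 0L)
  }
  dosage <- t(apply(gtm, c(1, 2), dose)[, , drop = FALSE])
  # dosage is now samples x sites
  miss_frac <- colMeans(is.na(dosage))
  keep <- (is.na(qual) | qual >= cfg$min_qual) &
    miss_frac <= cfg$max_missing
  keep[is.na(keep)] <- FALSE
  dosage <- dosage[, keep, drop = FALSE]
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  colnames(dosage) <- paste(sites$chrom, sites$pos, sep = ":")
  list(dosage = dosage, sites = sites)
}
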
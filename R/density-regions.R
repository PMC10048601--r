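#' Region detection configuration
#'
#' Settings for the window-density scan that flags putative introgressions.
#' Thresholds can be given as absolute per-window counts
#' (`mode = "absolute"`) or derived as `fold` times the genome-wide mean
#' per-window count (`mode = "fold_mean"`, the default).  A window
#' qualifies when its SNP count *or* its InDel count strictly exceeds the
#' corresponding threshold ("more than" semantics).
#'
#' @param window_bp window size in bp (default 1,000,000; non-overlapping).
#' @param mode `"fold_mean"` or `"absolute"`.
#' @param fold multiplier on the genome-wide mean window count
#'   (default 3), used in `fold_mean` mode.
#' @param snp_threshold,indel_threshold absolute per-window thresholds,
#'   required in `absolute` mode.
#' @param merge_gap_windows runs of qualifying windows separated by at
#'   most this many non-qualifying windows are merged (default 1).
#' @return A `region_config` list.
#' @export
region_config <- function(window_bp = 1e6,
                          mode = c("fold_mean", "absolute"),
                          fold = 3,
                          snp_threshold = NULL, indel_threshold = NULL,
                          merge_gap_windows = 1) {
  mode <- match.arg(mode)
  if (window_bp <= 0) stop_config("window_bp must be > 0")
  if (merge_gap_windows < 0) stop_config("merge_gap_windows must be >= 0")
  if (mode == "fold_mean" && fold <= 0) stop_config("fold must be > 0")
  if (mode == "absolute") {
    if (is.null(snp_threshold) || is.null(indel_threshold))
      stop_config("absolute mode requires snp_threshold and indel_threshold")
    if (snp_threshold <= 0 || indel_threshold <= 0)
      stop_config("thresholds must be > 0")
  }
  structure(list(window_bp = as.integer(window_bp), mode = mode, fold = fold,
                 snp_threshold = snp_threshold,
                 indel_threshold = indel_threshold,
                 merge_gap_windows = as.integer(merge_gap_windows)),
            class = "region_config")
}

#' Count SNPs and InDels in non-overlapping windows
#'
#' Tiles every chromosome with `window_bp`-sized windows (window `i`
#' covers `[(i-1)*W + 1, i*W]`, 1-based inclusive; the terminal window is
#' truncated at the chromosome end) and counts SNP and InDel records per
#' window.
#'
#' @param records variant-record `data.frame` (typically filtered).
#' @param chrom_lengths named integer vector of chromosome lengths; must
#'   cover every chromosome present in `records`.
#' @param cfg a [region_config()].
#' @return data.frame with chrom, start, end, snp_count, indel_count.
#' @export
count_in_windows <- function(records, chrom_lengths, cfg = region_config()) {
  missing_chr <- setdiff(unique(records$chrom), names(chrom_lengths))
  if (length(missing_chr) > 0)
    stop_data("chromosome length missing for: %s",
              paste(missing_chr, collapse = ", "))
  w <- cfg$window_bp
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- as.numeric(chrom_lengths[[chr]])
    nwin <- ceiling(len / w)
    start <- (seq_len(nwin) - 1) * w + 1
    end <- pmin(seq_len(nwin) * w, len)
    r <- records[records$chrom == chr, , drop = FALSE]
    if (any(r$pos > len))
      stop_data("variant position %d exceeds length of %s (%d)",
                max(r$pos), chr, as.integer(len))
    idx <- ((r$pos - 1) %/% w) + 1
    snp <- tabulate(idx[r$vclass == "SNP"], nbins = nwin)
    ind <- tabulate(idx[r$vclass == "InDel"], nbins = nwin)
    data.frame(chrom = chr, start = as.integer(start), end = as.integer(end),
               snp_count = snp, indel_count = ind, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Resolve per-window thresholds for a window table under a config.
region_thresholds <- function(windows, cfg) {
  if (cfg$mode == "absolute") {
    list(snp = cfg$snp_threshold, indel = cfg$indel_threshold)
  } else {
    list(snp = cfg$fold * mean(windows$snp_count),
         indel = cfg$fold * mean(windows$indel_count))
  }
}

#' Detect highly polymorphic regions from window counts
#'
#' Flags windows whose SNP or InDel count strictly exceeds its threshold,
#' merges runs of qualifying windows separated by at most
#' `merge_gap_windows` non-qualifying windows, and labels the merged
#' regions `p{chrom}_{k}` in genomic order per chromosome.  The `trigger`
#' column records which density exceeded its threshold anywhere in the
#' region (`snp`, `indel` or `both`).
#'
#' @param windows window table from [count_in_windows()], sorted by
#'   chromosome and start.
#' @param cfg a [region_config()].
#' @return data.frame with label, chrom, start, end, snp_total,
#'   indel_total, trigger, n_windows.
#' @export
detect_polymorphic_regions <- function(windows, cfg = region_config()) {
  if (nrow(windows) == 0) {
    return(data.frame(label = character(), chrom = character(),
                      start = integer(), end = integer(),
                      snp_total = integer(), indel_total = integer(),
                      trigger = character(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  }
  th <- region_thresholds(windows, cfg)
  regions <- list()
  for (chr in unique(windows$chrom)) {
    wc <- windows[windows$chrom == chr, , drop = FALSE]
    if (is.unsorted(wc$start, strictly = TRUE))
      stop_data("windows on %s are unsorted or overlapping", chr)
    if (any(diff(wc$start) != cfg$window_bp))
      stop_data("windows on %s do not tile the chromosome", chr)
    q_snp <- wc$snp_count > th$snp
    q_ind <- wc$indel_count > th$indel
    qual <- q_snp | q_ind
    if (!any(qual)) next
    qi <- which(qual)
    # merge qualifying windows whose gap is <= merge_gap_windows
    grp <- cumsum(c(1, diff(qi) > cfg$merge_gap_windows + 1L))
    k <- 0L
    for (g in unique(grp)) {
      idx <- qi[grp == g]
      span <- seq(min(idx), max(idx))
      k <- k + 1L
      trig_snp <- any(q_snp[idx])
      trig_ind <- any(q_ind[idx])
      regions[[length(regions) + 1L]] <- data.frame(
        label = sprintf("p%s_%d", chrom_token(chr), k),
        chrom = chr,
        start = wc$start[min(idx)],
        end = wc$end[max(idx)],
        snp_total = sum(wc$snp_count[span]),
        indel_total = sum(wc$indel_count[span]),
        trigger = if (trig_snp && trig_ind) "both"
                  else if (trig_snp) "snp" else "indel",
        n_windows = length(span),
        stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0) {
    return(detect_polymorphic_regions(windows[0, ], cfg))
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Write a window table as TSV
#' @param windows window table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) write_tsv_plain(windows, path)

#' Write polymorphic regions as TSV and/or BED
#'
#' The TSV keeps the package's 1-based inclusive coordinates; the BED
#' export converts to 0-based half-open.
#'
#' @param regions region table from [detect_polymorphic_regions()].
#' @param tsv_path,bed_path output paths (either may be `NULL`).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_regions <- function(regions, tsv_path = NULL, bed_path = NULL) {
  written <- character()
  if (!is.null(tsv_path)) {
    write_tsv_plain(regions, tsv_path)
    written <- c(written, tsv_path)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom,
                      start = regions$start - 1L,
                      end = regions$end,
                      name = regions$label,
                      stringsAsFactors = FALSE)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
    written <- c(written, bed_path)
  }
  invisible(written)
}

#' Read back a region TSV written by [write_regions()]
#' @param path TSV path.
#' @return region data.frame.
#' @export
read_regions_tsv <- function(path) read_tsv_plain(path)
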
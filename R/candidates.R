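#' Keyword configuration for candidate-list building
#'
#' Case-insensitive substring keywords used to screen gene functional
#' descriptions into a heat-response list and a reproduction list.  The
#' defaults follow the published search terms (heat/HSP/HSF and
#' flower/pollen/anthesis/anther/fruit set); chaperone vocabulary
#' (`dnaj`, `chaperone`) can be added to match annotation databases
#' whose HSP40 entries are described as DnaJ chaperones.
#'
#' @param heat_keywords character vector of heat-list keywords.
#' @param reproduction_keywords character vector of reproduction-list
#'   keywords.
#' @return A `keyword_config` list (keywords lowercase-normalized).
#' @export
keyword_config <- function(heat_keywords = c("heat", "hsp", "hsf"),
                           reproduction_keywords = c("flower", "pollen",
                                                     "anthesis", "anther",
                                                     "fruit set")) {
  if (length(heat_keywords) == 0 || length(reproduction_keywords) == 0)
    stop_config("keyword lists must be non-empty")
  structure(list(heat_keywords = tolower(heat_keywords),
                 reproduction_keywords = tolower(reproduction_keywords)),
            class = "keyword_config")
}

#' Annotation-vocabulary keyword set
#'
#' The default keywords extended with `dnaj` and `chaperone`, so HSP40
#' family members described as "Chaperone protein DnaJ" are captured by
#' the heat list, as they are in curated candidate tables.
#'
#' @return A [keyword_config()].
#' @export
annotation_keyword_config <- function() {
  keyword_config(heat_keywords = c("heat", "hsp", "hsf", "dnaj", "chaperone"))
}

match_any <- function(desc, keywords) {
  d <- tolower(desc)
  Reduce(`|`, lapply(keywords, function(k) grepl(k, d, fixed = TRUE)))
}

# Subcategory within a list, by first matching keyword group.
heat_subcategory <- function(desc) {
  d <- tolower(desc)
  hsf_terms <- c("hsf", "heat stress transcription factor",
                 "heat shock transcription factor", "heat shock factor")
  ifelse(match_any(d, hsf_terms), "HSF", "HSP")
}

reproduction_subcategory <- function(desc) {
  ifelse(match_any(desc, "flower"), "flower", "pollen")
}

#' Build keyword candidate lists from gene descriptions
#'
#' A gene joins a list iff any keyword is a case-insensitive substring
#' of its functional description; a gene can join both lists.  Heat-list
#' genes are subcategorized HSF (transcription-factor vocabulary) or HSP;
#' reproduction-list genes are subcategorized flower or pollen
#' (pollen/anther/anthesis terms).
#'
#' @param genes a [gene_models] object, or a data.frame with `gene_id`
#'   and `description` columns.
#' @param kw a [keyword_config()].
#' @return list with `heat` and `reproduction` data.frames (gene_id,
#'   description, subcategory) and `both` (ids present in both lists).
#' @export
keyword_select <- function(genes, kw = keyword_config()) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  stopifnot(all(c("gene_id", "description") %in% names(g)))
  in_heat <- match_any(g$description, kw$heat_keywords)
  in_rep <- match_any(g$description, kw$reproduction_keywords)
  heat <- g[in_heat, c("gene_id", "description"), drop = FALSE]
  heat$subcategory <- heat_subcategory(heat$description)
  rep_ <- g[in_rep, c("gene_id", "description"), drop = FALSE]
  rep_$subcategory <- reproduction_subcategory(rep_$description)
  rownames(heat) <- rownames(rep_) <- NULL
  list(heat = heat, reproduction = rep_,
       both = intersect(heat$gene_id, rep_$gene_id))
}

#' Colocalize genes with genomic intervals
#'
#' A gene overlaps an interval iff their 1-based inclusive spans share at
#' least one base.  Implemented on GenomicRanges.
#'
#' @param genes a [gene_models] object or data.frame with gene_id,
#'   chrom, tx_start, tx_end.
#' @param intervals data.frame with an id column (first of `qtl_id`,
#'   `label`, `id` found), chrom, start, end.
#' @return data.frame with gene_id, interval_id (zero rows when nothing
#'   overlaps).
#' @export
colocalize <- function(genes, intervals) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  id_col <- intersect(c("qtl_id", "label", "id"), names(intervals))[1]
  if (is.na(id_col)) stop_data("intervals need a qtl_id/label/id column")
  if (nrow(g) == 0 || nrow(intervals) == 0) {
    return(data.frame(gene_id = character(), interval_id = character(),
                      stringsAsFactors = FALSE))
  }
  unmatched <- setdiff(unique(intervals$chrom), unique(g$chrom))
  if (length(unmatched) == length(unique(intervals$chrom)))
    stop_data("no shared chromosome names; unmatched: %s",
              paste(unmatched, collapse = ", "),
              class = "introcand_namespace_error")
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$tx_start, g$tx_end))
  gr_i <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start,
                                                  intervals$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_i)
  data.frame(gene_id = g$gene_id[S4Vectors::queryHits(hits)],
             interval_id = intervals[[id_col]][S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Default flower-related QTL trait classes
#'
#' Trait classes whose QTLs count as "flower number related" for the
#' prioritization step.  The broader default (flower number, flowers per
#' inflorescence, inflorescence number, flowering time) reproduces
#' curated candidate tables that include flowering-time QTLs; use
#' `strict = TRUE` for flower number only.
#'
#' @param strict restrict to flower number only.
#' @return character vector of trait classes (lowercase).
#' @export
flower_trait_classes <- function(strict = FALSE) {
  if (strict) "flower number"
  else c("flower number", "flowers per inflorescence",
         "inflorescence number", "flowering time")
}

#' Prioritize candidate genes
#'
#' Selects genes that (1) belong to a keyword candidate list, (2) carry
#' at least one HIGH or MODERATE impact variant, and (3) lie in a
#' detected polymorphic region or overlap a QTL whose trait class is
#' flower related.  Output rows carry per-gene HIGH/MODERATE tallies,
#' the containing region label (or `NA`) and overlapping QTL ids, sorted
#' by chromosome then position.
#'
#' @param lists result of [keyword_select()].
#' @param annotations data.frame from [annotate_variants()].
#' @param genes a [gene_models] object (coordinates and descriptions).
#' @param regions polymorphic-region table (may have zero rows).
#' @param qtls QTL table with qtl_id, trait_class, chrom, start, end
#'   (may have zero rows).
#' @param flower_classes trait classes counting as flower related.
#' @return data.frame of candidate genes.
#' @export
prioritize <- function(lists, annotations, genes, regions, qtls,
                       flower_classes = flower_trait_classes()) {
  g <- genes$genes
  member <- rbind(
    if (nrow(lists$heat) > 0)
      data.frame(gene_id = lists$heat$gene_id, list = "heat",
                 subcategory = lists$heat$subcategory,
                 stringsAsFactors = FALSE),
    if (nrow(lists$reproduction) > 0)
      data.frame(gene_id = lists$reproduction$gene_id, list = "reproduction",
                 subcategory = lists$reproduction$subcategory,
                 stringsAsFactors = FALSE))
  if (is.null(member) || nrow(member) == 0) return(empty_candidates())

  sev <- annotations[!is.na(annotations$gene) &
                       annotations$impact %in% c("HIGH", "MODERATE"), ,
                     drop = FALSE]
  high_n <- table(sev$gene[sev$impact == "HIGH"])
  mod_n <- table(sev$gene[sev$impact == "MODERATE"])

  reg_hit <- if (nrow(regions) > 0) colocalize(genes, regions)
             else data.frame(gene_id = character(), interval_id = character())
  qtl_f <- qtls[tolower(qtls$trait_class) %in% tolower(flower_classes), ,
                drop = FALSE]
  qtl_hit <- if (nrow(qtl_f) > 0) colocalize(genes, qtl_f)
             else data.frame(gene_id = character(), interval_id = character())

  rows <- lapply(unique(member$gene_id), function(id) {
    hn <- if (id %in% names(high_n)) as.integer(high_n[[id]]) else 0L
    mn <- if (id %in% names(mod_n)) as.integer(mod_n[[id]]) else 0L
    if (hn + mn < 1L) return(NULL)
    regs <- reg_hit$interval_id[reg_hit$gene_id == id]
    qs <- sort(unique(qtl_hit$interval_id[qtl_hit$gene_id == id]))
    if (length(regs) == 0 && length(qs) == 0) return(NULL)
    m <- member[member$gene_id == id, , drop = FALSE][1, ]
    gi <- g[g$gene_id == id, ]
    data.frame(gene_id = id, list = m$list, subcategory = m$subcategory,
               high_n = hn, moderate_n = mn,
               region_label = if (length(regs) > 0) regs[1] else NA_character_,
               qtl_ids = if (length(qs) > 0) paste(qs, collapse = ";")
                         else NA_character_,
               chrom = gi$chrom, tx_start = gi$tx_start,
               description = gi$description, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$tx_start), ]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(gene_id = character(), list = character(),
             subcategory = character(), high_n = integer(),
             moderate_n = integer(), region_label = character(),
             qtl_ids = character(), chrom = character(),
             tx_start = integer(), description = character(),
             stringsAsFactors = FALSE)
}

#' Summarize a candidate-gene table
#'
#' Reports the totals used to audit a prioritized candidate set: total
#' genes, distinct polymorphic-region labels (excluding genes outside
#' regions), genes carrying at least one high-impact variant, and
#' per-list / per-subcategory counts.
#'
#' @param candidates data.frame from [prioritize()] or a fixture loader;
#'   needs columns high_n, region_label, list, subcategory.
#' @return list of summary counts.
#' @export
summarize_candidates <- function(candidates) {
  regions <- candidates$region_label
  regions <- regions[!is.na(regions) & regions != "-" & nzchar(regions)]
  by_list <- table(factor(candidates$list,
                          levels = c("heat", "reproduction")))
  by_sub <- table(factor(candidates$subcategory,
                         levels = c("HSP", "HSF", "flower", "pollen")))
  list(total = nrow(candidates),
       distinct_regions = length(unique(regions)),
       high_impact_genes = sum(candidates$high_n >= 1),
       by_list = as.list(as.integer(by_list)) |>
         stats::setNames(names(by_list)),
       by_subcategory = as.list(as.integer(by_sub)) |>
         stats::setNames(names(by_sub)))
}

#' Load the packaged E42 candidate-gene table
#'
#' The curated 35-gene candidate table for the heat-tolerant tomato line
#' E42 (gene id, counts of high/moderate impact variants, polymorphic
#' region, colocalized QTLs, protein function), shipped as a plain-text
#' fixture.  List membership and subcategory are assigned by
#' [keyword_select()] on the protein-function column.
#'
#' @param kw keyword set used to classify the descriptions; defaults to
#'   the annotation-vocabulary set (see [annotation_keyword_config()]).
#' @return data.frame in the shape consumed by [summarize_candidates()].
#' @export
load_candidate_table <- function(kw = annotation_keyword_config()) {
  path <- system.file("extdata", "e42_candidate_genes.tsv",
                      package = "introcand", mustWork = TRUE)
  tab <- read_tsv_plain(path)
  sel <- keyword_select(data.frame(gene_id = tab$gene,
                                   description = tab$protein_function,
                                   stringsAsFactors = FALSE), kw)
  lst <- rep(NA_character_, nrow(tab))
  sub <- rep(NA_character_, nrow(tab))
  lst[tab$gene %in% sel$heat$gene_id] <- "heat"
  sub[tab$gene %in% sel$heat$gene_id] <-
    sel$heat$subcategory[match(tab$gene[tab$gene %in% sel$heat$gene_id],
                               sel$heat$gene_id)]
  is_rep <- tab$gene %in% sel$reproduction$gene_id & is.na(lst)
  lst[is_rep] <- "reproduction"
  sub[is_rep] <- sel$reproduction$subcategory[
    match(tab$gene[is_rep], sel$reproduction$gene_id)]
  data.frame(gene_id = tab$gene, list = lst, subcategory = sub,
             high_n = tab$high_n, moderate_n = tab$moderate_n,
             region_label = ifelse(tab$region == "-", NA_character_,
                                   tab$region),
             qtl_ids = ifelse(tab$qtl == "-", NA_character_, tab$qtl),
             description = tab$protein_function,
             stringsAsFactors = FALSE)
}

#' Load the packaged reproductive-QTL trait counts
#'
#' Published per-trait counts and chromosome distribution of the 86
#' reproductive-trait QTLs curated from the tomato literature.
#'
#' @return data.frame with trait, qtl_n, chromosomes.
#' @export
load_qtl_trait_counts <- function() {
  path <- system.file("extdata", "reproductive_qtl_counts.tsv",
                      package = "introcand", mustWork = TRUE)
  read_tsv_plain(path)
}

#' Write a candidate table as TSV
#' @param candidates candidate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  write_tsv_plain(candidates, path)
}
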
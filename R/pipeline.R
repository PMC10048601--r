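#' Pipeline configuration
#'
#' Declarative configuration of the end-to-end analysis.  Inputs come
#' either from a simulation block (`simulate = sim_config(...)`) or
#' from files (reference FASTA, GFF3 gene models, focal VCF and
#' optionally panel/donor VCFs and a QTL TSV) -- never a mixture of
#' missing pieces.  `mode = "fixtures"` instead summarizes the packaged
#' curated candidate table.
#'
#' @param mode `"simulate"`, `"files"` or `"fixtures"`.
#' @param simulate a [sim_config()] (simulate mode).
#' @param reference_fa,genes_gff3,focal_vcf,panel_vcf,donor_vcf,qtl_tsv
#'   input paths (files mode; panel/donor/qtl optional).
#' @param motif_catalog_tsv motif catalog path (`NULL` = packaged
#'   default).
#' @param filter a [filter_config()].
#' @param region a [region_config()].
#' @param keywords a [keyword_config()].
#' @param flower_classes QTL trait classes counting as flower related.
#' @param promoter_bp promoter length for the cis-element comparison.
#' @param flank_bp up/downstream flank for effect annotation.
#' @param focal_name focal sample name in the panel.
#' @param out_dir output directory.
#' @param seed integer seed (simulate mode randomness).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "files", "fixtures"),
                            simulate = NULL,
                            reference_fa = NULL, genes_gff3 = NULL,
                            focal_vcf = NULL, panel_vcf = NULL,
                            donor_vcf = NULL, qtl_tsv = NULL,
                            motif_catalog_tsv = NULL,
                            filter = filter_config(),
                            region = region_config(),
                            keywords = keyword_config(),
                            flower_classes = flower_trait_classes(),
                            promoter_bp = 3000, flank_bp = 5000,
                            focal_name = "E42",
                            out_dir = tempfile("introcand_run_"),
                            seed = 1) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(simulate)) simulate <- sim_config(seed = seed)
    validate_sim_config(simulate)
  }
  if (mode == "files") {
    need <- c(reference_fa = reference_fa, genes_gff3 = genes_gff3,
              focal_vcf = focal_vcf)
    if (length(need) < 3 || any(!nzchar(need)))
      stop_config("files mode requires reference_fa, genes_gff3, focal_vcf")
    missing <- need[!file.exists(need)]
    if (length(missing) > 0)
      stop_config("input file(s) not found: %s",
                  paste(missing, collapse = ", "))
  }
  structure(list(mode = mode, simulate = simulate,
                 reference_fa = reference_fa, genes_gff3 = genes_gff3,
                 focal_vcf = focal_vcf, panel_vcf = panel_vcf,
                 donor_vcf = donor_vcf, qtl_tsv = qtl_tsv,
                 motif_catalog_tsv = motif_catalog_tsv,
                 filter = filter, region = region, keywords = keywords,
                 flower_classes = flower_classes,
                 promoter_bp = promoter_bp, flank_bp = flank_bp,
                 focal_name = focal_name, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Extract reference + focal promoter sequences for one gene.
promoter_pair <- function(gm, gene_id, genome, focal_variants, length_bp) {
  g <- gene_row(gm, gene_id)
  win <- promoter_window(g, length_bp)
  win[1] <- max(1L, win[1])
  win[2] <- min(length(genome[[g$chrom]]), win[2])
  ref_fwd <- Biostrings::subseq(genome[[g$chrom]], win[1], win[2])
  v <- focal_variants[focal_variants$chrom == g$chrom &
                        focal_variants$pos >= win[1] &
                        focal_variants$pos + nchar(focal_variants$ref) - 1 <=
                          win[2], , drop = FALSE]
  foc_fwd <- apply_variants(ref_fwd, v, offset = win[1] - 1L)
  if (g$strand == "-") {
    ref_fwd <- Biostrings::reverseComplement(ref_fwd)
    foc_fwd <- Biostrings::reverseComplement(foc_fwd)
  }
  list(ref = ref_fwd, focal = foc_fwd)
}

#' Run the end-to-end candidate-gene pipeline
#'
#' Executes filter, window counting, region detection, effect
#' annotation, keyword/QTL prioritization, per-chromosome phylogeny and
#' origin assignment, promoter cis-element comparison and donor-sharing
#' classification, writing all tabular outputs plus a run manifest to
#' `cfg$out_dir`.  Two runs with an identical configuration produce
#' byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(name, file) {
    paths[[name]] <<- file.path(cfg$out_dir, file)
    paths[[name]]
  }

  if (cfg$mode == "fixtures") {
    cand <- load_candidate_table()
    summary <- summarize_candidates(cand)
    qtl_counts <- load_qtl_trait_counts()
    summary$qtl_total <- sum(qtl_counts$qtl_n)
    summary$qtl_flowering_time <-
      qtl_counts$qtl_n[qtl_counts$trait == "Flowering time"]
    write_candidates_tsv(cand, emit("candidates", "candidates.tsv"))
    jsonlite::write_json(summary, emit("summary", "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res <- list(candidates = cand, summary = summary, paths = paths)
    return(invisible(res))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_data("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # ---- inputs -------------------------------------------------------------
  if (cfg$mode == "simulate") {
    sim <- stage("simulate",
                 simulate_dataset(cfg$simulate,
                                  dir = file.path(cfg$out_dir, "inputs")))
    genome <- sim$reference
    gm <- sim$genes
    focal_raw <- sim$focal
    panel <- sim$panel
    species_of <- sim$panel$species_of
    focal_name <- sim$panel$focal
    donor <- sim$donor
    qtls <- sim$qtls
    catalog <- sim$motif_catalog
    truth <- sim$truth
  } else {
    genome <- stage("read_reference",
                    Biostrings::readDNAStringSet(cfg$reference_fa))
    names(genome) <- sub("\\s.*$", "", names(genome))
    gm <- stage("read_genes", read_gene_models_gff3(cfg$genes_gff3))
    focal_raw <- stage("read_focal", read_variants(cfg$focal_vcf))
    panel <- if (!is.null(cfg$panel_vcf))
      stage("read_panel", read_genotype_matrix(cfg$panel_vcf, cfg$filter))
    else NULL
    if (!is.null(panel)) {
      samples <- rownames(panel$dosage)
      others <- setdiff(samples, cfg$focal_name)
      species_of <- stats::setNames(sub("_[0-9]+$", "", others), others)
    } else species_of <- NULL
    focal_name <- cfg$focal_name
    donor <- if (!is.null(cfg$donor_vcf))
      stage("read_donor", read_variants(cfg$donor_vcf)) else NULL
    qtls <- if (!is.null(cfg$qtl_tsv)) read_tsv_plain(cfg$qtl_tsv) else NULL
    catalog <- read_motif_catalog(cfg$motif_catalog_tsv)
    truth <- NULL
  }
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  # ---- filter -> windows -> regions --------------------------------------
  filtered <- stage("filter", filter_variants(focal_raw, cfg$filter))
  windows <- stage("windows",
                   count_in_windows(filtered, chrom_lengths, cfg$region))
  regions <- stage("regions",
                   detect_polymorphic_regions(windows, cfg$region))

  # ---- effect annotation --------------------------------------------------
  annotations <- stage("annotate",
                       annotate_variants(filtered, gm, genome, cfg$flank_bp))
  impacts <- summarize_impacts(annotations)

  # ---- candidate lists and prioritization ---------------------------------
  lists <- stage("keywords", keyword_select(gm, cfg$keywords))
  candidates <- if (!is.null(qtls)) {
    stage("prioritize", prioritize(lists, annotations, gm, regions, qtls,
                                   cfg$flower_classes))
  } else {
    stage("prioritize", prioritize(lists, annotations, gm, regions,
                                   data.frame(qtl_id = character(),
                                              trait_class = character(),
                                              chrom = character(),
                                              start = integer(),
                                              end = integer()),
                                   cfg$flower_classes))
  }

  # ---- per-chromosome phylogeny and origin --------------------------------
  phylo <- NULL
  if (!is.null(panel)) {
    newick_dir <- file.path(cfg$out_dir, "trees")
    dir.create(newick_dir, showWarnings = FALSE)
    phylo <- stage("phylogeny",
                   chromosome_trees(panel, focal_name, species_of,
                                    newick_dir = newick_dir))
  }

  # ---- promoter comparison ------------------------------------------------
  promoter_cmp <- NULL
  if (nrow(candidates) > 0) {
    promoter_cmp <- stage("promoters", {
      rows <- lapply(candidates$gene_id, function(id) {
        pp <- promoter_pair(gm, id, genome, filtered, cfg$promoter_bp)
        cmp <- compare_promoters(pp$ref, pp$focal, catalog)
        data.frame(gene_id = id, mutated_n = cmp$mutated_total,
                   hse_reference = cmp$hse_present_a,
                   hse_focal = cmp$hse_present_b,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }

  # ---- donor sharing ------------------------------------------------------
  sharing <- NULL
  if (!is.null(donor) && nrow(candidates) > 0) {
    sharing <- stage("sharing",
                     sharing_report(candidates$gene_id, gm, genome,
                                    filtered, donor, annotations))
  }

  # ---- outputs ------------------------------------------------------------
  write_variants_tsv(filtered, emit("filtered", "filtered_variants.tsv"))
  write_window_table(windows, emit("windows", "windows.tsv"))
  write_regions(regions, tsv_path = emit("regions", "regions.tsv"),
                bed_path = emit("regions_bed", "regions.bed"))
  write_annotations_tsv(annotations, emit("annotations", "annotations.tsv"))
  write_candidates_tsv(candidates, emit("candidates", "candidates.tsv"))
  if (!is.null(phylo))
    write_tsv_plain(phylo$origins, emit("origins", "origins.tsv"))
  if (!is.null(promoter_cmp))
    write_tsv_plain(promoter_cmp,
                    emit("promoters", "promoter_comparison.tsv"))
  if (!is.null(sharing))
    write_tsv_plain(sharing, emit("sharing", "sharing.tsv"))

  summary <- c(summarize_candidates(candidates),
               list(n_variants_raw = nrow(focal_raw),
                    n_variants_filtered = nrow(filtered),
                    n_regions = nrow(regions),
                    impact_percent = stats::setNames(
                      as.list(impacts$by_impact$percent),
                      impacts$by_impact$impact)))
  if (!is.null(phylo)) {
    top <- phylo$origins[phylo$origins$rank == 1, ]
    summary$origin_top <- stats::setNames(as.list(top$species), top$chrom)
  }
  jsonlite::write_json(summary, emit("summary", "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_json <- jsonlite::serializeJSON(cfg[setdiff(names(cfg), "out_dir")])
  cfg_tmp <- file.path(cfg$out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_tmp)
  files <- sort(unlist(paths))
  manifest <- list(
    package = "introcand",
    version = as.character(utils::packageVersion("introcand")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")

  invisible(list(config = cfg, genome = genome, genes = gm,
                 focal_raw = focal_raw, filtered = filtered,
                 windows = windows, regions = regions,
                 annotations = annotations, impacts = impacts,
                 lists = lists, candidates = candidates, phylo = phylo,
                 promoter_cmp = promoter_cmp, sharing = sharing,
                 qtls = qtls, truth = truth, summary = summary,
                 paths = paths))
}
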
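# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded package
#' operations never disturb global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# IUPAC nucleotide codes -> character vector of matching bases.
iupac_table <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

is_iupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(iupac_table()))
}

# Reverse complement of a plain character string (IUPAC-aware).
revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  chars <- rev(strsplit(toupper(x), "")[[1]])
  paste(comp[chars], collapse = "")
}

# Strip a leading "chr"/"chrom" prefix and zero padding from a chromosome
# name, for compact region labels like "p1_5".
chrom_token <- function(chrom) {
  tok <- sub("^[Cc][Hh][Rr]([Oo][Mm])?(osome)?[._]?", "", chrom)
  tok2 <- sub("^0+", "", tok)
  ifelse(nchar(tok2) > 0, tok2, tok)
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("introcand_config_error", "error")))
}

stop_data <- function(fmt, ..., class = "introcand_data_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

# Deterministic TSV writer (no quoting surprises, fixed EOLs).
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
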
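#' Construct a gene set
#'
#' A gene set is a labelled, deduplicated collection of gene identifiers.
#'
#' @param label Short non-empty name for the set (e.g. `"target"`).
#' @param genes Character vector of gene identifiers; whitespace is
#'   stripped and duplicates removed.
#' @return An object of class `gene_set` with elements `label` and
#'   `genes`.
#' @export
#' @examples
#' gene_set("target", c("TP53", "EGFR"))
gene_set <- function(label, genes) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string", call. = FALSE)
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) genes <- unique(genes)
  if (length(genes) == 0L)
    stop("gene set '", label, "' is empty", call. = FALSE)
  structure(list(label = label, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> '", x$label, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene list from a text file
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; surrounding whitespace is stripped. Duplicate identifiers are
#' collapsed with a warning.
#'
#' @param path Path to the text file.
#' @param label Label for the resulting set; defaults to the file name
#'   without extension.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no gene identifiers in ", path, call. = FALSE)
  ndup <- sum(duplicated(lines))
  if (ndup > 0L)
    warning(ndup, " duplicate identifier(s) in ", path, call. = FALSE)
  gene_set(label %||% sub("\\.[^.]*$", "", basename(path)), lines)
}

#' Read a gene-to-family map
#'
#' Parses a two-column tab-separated file (`gene<TAB>family_accession`,
#' header line required, one row per gene/family pair) into a family map:
#' a named list mapping each gene to its set of family accessions.
#'
#' @param path Path to the TSV file.
#' @return Named list of character vectors (class `family_map`).
#' @export
read_family_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("family file must have two tab-separated columns: ", path,
         call. = FALSE)
  fam <- split(trimws(df[[2L]]), trimws(df[[1L]]))
  family_map(lapply(fam, unique))
}

#' Construct a family map
#'
#' @param x Named list: gene identifier -> character vector of family
#'   accessions (each non-empty).
#' @return The validated list with class `family_map`.
#' @export
family_map <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("family map must be a named list", call. = FALSE)
  if (any(lengths(x) == 0L))
    stop("every gene in a family map needs at least one family",
         call. = FALSE)
  structure(x, class = "family_map")
}

#' Derive the non-target control set by family exclusion
#'
#' Returns the genes of the family map whose family assignments share no
#' family with any target gene. This implements the control-set
#' construction in which "non-targets" are proteins with no domain
#' family in common with any target protein: whole families containing a
#' target are filtered out, the targets themselves are always excluded,
#' and genes absent from the family map are never returned (their domain
#' dissimilarity cannot be certified).
#'
#' @param targets A [gene_set()] of target genes.
#' @param families A [family_map()].
#' @param label Label for the returned set (default `"nontarget"`).
#' @return A [gene_set()] of eligible non-target genes.
#' @export
derive_nontargets <- function(targets, families, label = "nontarget") {
  stopifnot(inherits(targets, "gene_set"))
  if (length(families) == 0L) stop("empty family map", call. = FALSE)
  tg <- targets$genes
  in_map <- tg[tg %in% names(families)]
  if (length(in_map) == 0L)
    warning("no target gene is present in the family map; ",
            "no families will be excluded", call. = FALSE)
  target_fams <- unique(unlist(families[in_map], use.names = FALSE))
  keep <- vapply(families, function(f) !any(f %in% target_fams), logical(1L))
  out <- setdiff(names(families)[keep], tg)
  if (length(out) == 0L)
    stop("family exclusion leaves no eligible non-target genes",
         call. = FALSE)
  gene_set(label, out)
}
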
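ORTHOLOG_COLUMNS <- c("human_gene", "species", "ortholog_gene",
                      "homology_type", "dn", "ds")

#' Read a BioMart-style ortholog table
#'
#' Parses a tab-separated ortholog export with header columns
#' `human_gene`, `species`, `ortholog_gene`, `homology_type`, `dn`, `ds`.
#' Missing dN/dS values may be encoded as empty fields or `NA`. Rows with
#' malformed or negative numeric fields are rejected with a warning that
#' lists the offending line numbers. A duplicated one-to-one record for
#' the same (gene, species) pair is a load error.
#'
#' @param path Path to the TSV file.
#' @param panel Character vector of admissible species codes, or `NULL`
#'   to accept any code. Defaults to [species_panel()].
#' @return A `data.frame` of class `ortholog_table` with the six typed
#'   columns (`dn`, `ds` numeric, possibly `NA`).
#' @export
read_ortholog_table <- function(path, panel = species_panel()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(ORTHOLOG_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("ortholog table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[ORTHOLOG_COLUMNS]

  parse_rate <- function(x) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & nzchar(x) & toupper(x) != "NA" & is.na(out)
    list(value = out, malformed = bad)
  }
  dn <- parse_rate(df$dn)
  ds <- parse_rate(df$ds)
  bad <- dn$malformed | ds$malformed |
    (!is.na(dn$value) & dn$value < 0) | (!is.na(ds$value) & ds$value < 0)
  if (any(bad)) {
    # +1 for the header line
    warning(sum(bad), " row(s) rejected (malformed or negative dN/dS) ",
            "at line(s): ", paste(which(bad) + 1L, collapse = ", "),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    dn$value <- dn$value[!bad]
    ds$value <- ds$value[!bad]
  }
  df$dn <- dn$value
  df$ds <- ds$value

  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$species), panel)
    if (length(unknown) > 0L)
      stop("unknown species code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  ortholog_table(df)
}

#' Construct / validate an ortholog table
#'
#' @param df A data.frame with the six ortholog columns.
#' @return `df` with class `ortholog_table`.
#' @export
ortholog_table <- function(df) {
  stopifnot(is.data.frame(df), all(ORTHOLOG_COLUMNS %in% names(df)))
  one2one <- df$homology_type == "ortholog_one2one"
  key <- paste(df$human_gene, df$species, sep = "\r")
  if (anyDuplicated(key[one2one]))
    stop("duplicate one-to-one record(s) for: ",
         paste(unique(sub("\r", "/", key[one2one][duplicated(key[one2one])])),
               collapse = ", "), call. = FALSE)
  if (any(df$dn < 0, na.rm = TRUE) || any(df$ds < 0, na.rm = TRUE))
    stop("negative dN or dS values", call. = FALSE)
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Species present in an ortholog table
#' @param table An `ortholog_table`.
#' @return Character vector of distinct species codes.
#' @export
table_species <- function(table) sort(unique(table$species))

#' Per-gene evolutionary rates (dN/dS) for one species
#'
#' For each gene of `genes` that has a one-to-one ortholog record for
#' `species` with both dN and dS present and dS > 0, returns the
#' evolutionary rate omega = dN/dS. All other genes are omitted; the
#' counts of exclusions by reason are attached as the `"excluded"`
#' attribute (`no_record`, `wrong_type`, `missing_value`, `ds_zero`).
#'
#' @param table An `ortholog_table`.
#' @param genes A [gene_set()].
#' @param species A species code present in the table.
#' @return `data.frame` with columns `human_gene`, `species`, `omega`.
#' @export
evolutionary_rates <- function(table, genes, species) {
  stopifnot(inherits(table, "ortholog_table"), inherits(genes, "gene_set"))
  if (!species %in% table$species)
    stop("species '", species, "' absent from the ortholog table",
         call. = FALSE)
  sub <- table[table$species == species & table$human_gene %in% genes$genes, ,
               drop = FALSE]
  one2one <- sub[sub$homology_type == "ortholog_one2one", , drop = FALSE]
  has_values <- !is.na(one2one$dn) & !is.na(one2one$ds)
  usable <- has_values & one2one$ds > 0
  kept <- one2one[usable, , drop = FALSE]

  genes_with_rows <- unique(sub$human_gene)
  excluded <- c(
    no_record = sum(!genes$genes %in% genes_with_rows),
    wrong_type = length(setdiff(genes_with_rows, one2one$human_gene)),
    missing_value = sum(!has_values),
    ds_zero = sum(has_values & one2one$ds == 0)
  )
  out <- data.frame(human_gene = kept$human_gene,
                    species = rep(species, nrow(kept)),
                    omega = if (nrow(kept)) kept$dn / kept$ds else numeric(0),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Percentage of genes with a one-to-one ortholog in a species
#'
#' The denominator is the full gene set, so genes with no orthology data
#' at all count against the percentage; dN/dS presence is irrelevant.
#'
#' @inheritParams evolutionary_rates
#' @return A percentage in \[0, 100\].
#' @export
ortholog_percentage <- function(table, genes, species) {
  stopifnot(inherits(table, "ortholog_table"), inherits(genes, "gene_set"))
  if (length(genes$genes) == 0L) stop("empty gene set", call. = FALSE)
  hit <- table$species == species &
    table$homology_type == "ortholog_one2one" &
    table$human_gene %in% genes$genes
  100 * length(unique(table$human_gene[hit])) / length(genes$genes)
}
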
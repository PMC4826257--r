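AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y", "X")

.consurvey_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 amino acids plus X
#'
#' The 20x20 core is the standard BLOSUM62 matrix (taken from the copy
#' shipped with Biostrings). The unknown residue X scores 0 against every
#' standard residue and -1 against X; this fixed convention keeps
#' self-alignment scores of X-free sequences unchanged while penalising
#' runs of unknowns.
#'
#' @return A symmetric 21x21 integer matrix with dimnames over
#'   `c(A R N D C Q E G H I L K M F P S T W V Y X)`.
#' @export
blosum62_matrix <- function() {
  if (!is.null(.consurvey_cache$blosum62)) return(.consurvey_cache$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  core <- env$BLOSUM62[AA_ALPHABET[1:20], AA_ALPHABET[1:20]]
  m <- matrix(0L, 21L, 21L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m[1:20, 1:20] <- as.integer(core)
  m["X", "X"] <- -1L
  storage.mode(m) <- "integer"
  .consurvey_cache$blosum62 <- m
  m
}

#' Construct an alignment scoring scheme
#'
#' Affine gap model: a gap of length L costs `gap_open + L * gap_extend`
#' (so a length-1 gap costs `gap_open + gap_extend`, the BLAST
#' convention). Defaults are the BLASTP defaults for BLOSUM62.
#'
#' @param matrix Symmetric integer substitution matrix with residue
#'   dimnames; default [blosum62_matrix()].
#' @param gap_open Positive integer gap-opening penalty (default 11).
#' @param gap_extend Positive integer gap-extension penalty (default 1);
#'   must not exceed `gap_open`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L) {
  matrix <- matrix %||% blosum62_matrix()
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) ||
      is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with matching dimnames",
         call. = FALSE)
  if (!isTRUE(all(matrix == t(matrix))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gap_open <= 0L || gap_extend <= 0L || gap_extend > gap_open)
    stop("need 0 < gap_extend <= gap_open", call. = FALSE)
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Read a substitution matrix in NCBI text format
#'
#' Lines starting with `#` are comments; the first data line lists the
#' column residues; each following line is a residue followed by its
#' integer scores.
#'
#' @param path Path to the matrix file.
#' @return A symmetric integer matrix usable in [scoring_scheme()].
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("not a matrix file: ", path, call. = FALSE)
  cols <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- strsplit(lines[-1L], "\\s+")
  res <- vapply(rows, `[`, character(1L), 1L)
  m <- t(vapply(rows, function(r) as.integer(r[-1L]),
                integer(length(cols))))
  dimnames(m) <- list(res, cols)
  m <- m[, res, drop = FALSE]  # keep square in row order
  m
}

#' Read protein sequences from a FASTA file
#'
#' Record identifiers are the header token up to the first whitespace.
#' Sequences are uppercased and must use only the 20 standard amino-acid
#' letters plus X; duplicate identifiers and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad))
    stop("illegal residue letters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence(s) in ", path, call. = FALSE)
  setNames(seqs, ids)
}

encode_residues <- function(seq, alphabet) {
  idx <- match(strsplit(seq, "")[[1L]], alphabet)
  if (anyNA(idx))
    stop("residue(s) outside the scoring alphabet", call. = FALSE)
  idx - 1L
}

#' Optimal Smith-Waterman local alignment score
#'
#' Exact optimal local-alignment score under the scheme's substitution
#' matrix and affine gap penalties, computed by the Gotoh dynamic
#' program. The empty alignment is admissible, so the score is always
#' >= 0; the score is symmetric in its arguments. This is the package's
#' deterministic stand-in for heuristic BLASTP raw scores.
#'
#' @param a,b Residue strings (uppercase, letters present in the
#'   scheme's matrix).
#' @param scheme A [scoring_scheme()]; default BLOSUM62 with gap
#'   penalties 11/1.
#' @return Non-negative integer score.
#' @export
#' @examples
#' local_alignment_score("AAAA", "AAAA")  # 16 = 4 * BLOSUM62(A, A)
local_alignment_score <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  alpha <- rownames(scheme$matrix)
  .sw_score_cpp(encode_residues(a, alpha), encode_residues(b, alpha),
                scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

#' Conservation scores for a gene set in one species
#'
#' Aligns each human protein to its species ortholog and reports the raw
#' local-alignment score as the conservation score (higher = more
#' conserved). The two sequence collections must cover the same
#' identifier set; genes of `genes` absent from the collections are
#' omitted and counted in the `"omitted"` attribute.
#'
#' @param human,ortholog Named character vectors of protein sequences
#'   (as from [read_fasta()]) or paths to FASTA files, with matching
#'   identifier sets.
#' @param genes A [gene_set()].
#' @param species Species code recorded in the output.
#' @param scheme A [scoring_scheme()].
#' @return `data.frame` with columns `human_gene`, `species`, `score`.
#' @export
conservation_scores <- function(human, ortholog, genes, species,
                                scheme = scoring_scheme()) {
  stopifnot(inherits(genes, "gene_set"))
  if (is.character(human) && length(human) == 1L && is.null(names(human)))
    human <- read_fasta(human)
  if (is.character(ortholog) && length(ortholog) == 1L &&
      is.null(names(ortholog)))
    ortholog <- read_fasta(ortholog)
  if (!setequal(names(human), names(ortholog)))
    stop("human and ortholog FASTA identifier sets differ", call. = FALSE)
  present <- intersect(genes$genes, names(human))
  omitted <- length(genes$genes) - length(present)
  if (omitted > 0L)
    message(omitted, " gene(s) without sequence pair omitted for ", species)
  alpha <- rownames(scheme$matrix)
  a <- lapply(human[present], encode_residues, alphabet = alpha)
  b <- lapply(unname(ortholog[present]), encode_residues, alphabet = alpha)
  scores <- if (length(present))
    .sw_scores_cpp(a, b, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  else integer(0)
  out <- data.frame(human_gene = present,
                    species = rep(species, length(present)),
                    score = scores, stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  out
}
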
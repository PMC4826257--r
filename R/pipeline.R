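comparison_table <- function(rows, feature, labels, cross = NULL) {
  structure(rows, feature = feature, labels = labels,
            cross_species = cross,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> feature '%s' (%s vs %s), %d row(s)\n",
              attr(x, "feature"), attr(x, "labels")[1L],
              attr(x, "labels")[2L], nrow(x)))
  print.data.frame(x, ...)
  cross <- attr(x, "cross_species")
  if (!is.null(cross)) {
    cat("cross-species: ")
    print(cross)
  }
  invisible(x)
}

#' Cross-species test result of a comparison table
#' @param x A `comparison_table`.
#' @return The `wilcoxon_result` of the cross-species signed-rank test,
#'   or `NULL` for network features.
#' @export
cross_species_test <- function(x) attr(x, "cross_species")

#' Compare one per-species feature between two groups
#'
#' For each species, both groups are summarised (median/quartiles) and
#' compared with a Wilcoxon rank-sum test (normal approximation with tie
#' and continuity corrections -- group sizes are typically in the
#' hundreds). Across species, the per-species medians of the two groups
#' are compared with a Wilcoxon signed-rank test; its default variant is
#' the normal approximation with continuity correction and *without*
#' tie correction.
#'
#' @param by_species Named list (one element per species), each a list
#'   of two non-empty numeric vectors: the group-1 and group-2 values.
#' @param feature Feature name recorded in the table.
#' @param labels Character vector of the two group labels.
#' @param cross_method,cross_tie_correction Variant of the
#'   cross-species signed-rank test (see [signed_rank_test()]).
#' @return A `comparison_table`: one row per species with both group
#'   summaries and `rank_sum_p`, and the cross-species `wilcoxon_result`
#'   as the `"cross_species"` attribute.
#' @export
compare_feature <- function(by_species, feature = "feature",
                            labels = c("target", "nontarget"),
                            cross_method = c("normal_approx", "exact"),
                            cross_tie_correction = FALSE) {
  cross_method <- match.arg(cross_method)
  if (length(by_species) == 0L || is.null(names(by_species)))
    stop("`by_species` must be a non-empty named list", call. = FALSE)
  rows <- lapply(names(by_species), function(sp) {
    v1 <- by_species[[sp]][[1L]]
    v2 <- by_species[[sp]][[2L]]
    if (length(v1) == 0L || length(v2) == 0L) {
      warning("species '", sp, "' has an empty group; no test performed",
              call. = FALSE)
      return(data.frame(species = sp, n1 = length(v1), median1 = NA_real_,
                        lower1 = NA_real_, upper1 = NA_real_,
                        n2 = length(v2), median2 = NA_real_,
                        lower2 = NA_real_, upper2 = NA_real_,
                        rank_sum_p = NA_real_, stringsAsFactors = FALSE))
    }
    s1 <- summarize_values(v1)
    s2 <- summarize_values(v2)
    rs <- rank_sum_test(v1, v2, method = "normal_approx",
                        continuity = TRUE, tie_correction = TRUE)
    data.frame(species = sp, n1 = s1$n, median1 = s1$median,
               lower1 = s1$lower_quartile, upper1 = s1$upper_quartile,
               n2 = s2$n, median2 = s2$median,
               lower2 = s2$lower_quartile, upper2 = s2$upper_quartile,
               rank_sum_p = rs$p_two_sided, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  ok <- !is.na(rows$median1) & !is.na(rows$median2)
  cross <- NULL
  if (sum(ok) >= 1L)
    cross <- tryCatch(
      signed_rank_test(rows$median1[ok], rows$median2[ok],
                       method = cross_method,
                       continuity = TRUE,
                       tie_correction = cross_tie_correction),
      error = function(e) {
        warning("cross-species test unavailable: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  comparison_table(rows, feature, labels, cross)
}

#' Compare per-species ortholog percentages between two gene sets
#'
#' One percentage per group per species (a single number, so no
#' per-species rank-sum test); across species, the 21 paired
#' percentages are compared with the *exact* Wilcoxon signed-rank test
#' by default (n = 21, ties not expected).
#'
#' @param table An [ortholog_table()].
#' @param targets,nontargets [gene_set()]s.
#' @param panel Character vector of species codes to cover.
#' @param cross_method Signed-rank variant for the cross-species test.
#' @return A `comparison_table` with columns `species`, `pct1`, `pct2`.
#' @export
compare_ortholog_percentages <- function(table, targets, nontargets,
                                         panel = table_species(table),
                                         cross_method = c("exact",
                                                          "normal_approx")) {
  cross_method <- match.arg(cross_method)
  if (length(panel) == 0L)
    stop("empty species panel", call. = FALSE)
  rows <- do.call(rbind, lapply(panel, function(sp) {
    data.frame(species = sp,
               pct1 = ortholog_percentage(table, targets, sp),
               pct2 = ortholog_percentage(table, nontargets, sp),
               stringsAsFactors = FALSE)
  }))
  cross <- signed_rank_test(rows$pct1, rows$pct2, method = cross_method)
  comparison_table(rows, "ortholog_percentage",
                   c(targets$label, nontargets$label), cross)
}

#' Compare network topology metrics between two gene sets
#'
#' Four rows -- degree, clustering coefficient, betweenness centrality,
#' average shortest path length -- each comparing the node metrics of
#' the two gene sets with a Wilcoxon rank-sum test (normal
#' approximation). Genes absent from the network are excluded; isolated
#' nodes contribute no ASPL value.
#'
#' @param net An undirected simple igraph.
#' @param targets,nontargets [gene_set()]s.
#' @return A `comparison_table` with one row per metric (the `species`
#'   column holds `"(network)"` and the metric name is in `feature`).
#' @export
compare_topology <- function(net, targets, nontargets) {
  t1 <- topology_table(net, targets)
  t2 <- topology_table(net, nontargets)
  if (nrow(t1) == 0L || nrow(t2) == 0L)
    stop("a gene set is disjoint from the network", call. = FALSE)
  metrics <- c("degree", "clustering", "betweenness", "aspl")
  rows <- do.call(rbind, lapply(metrics, function(mt) {
    v1 <- t1[[mt]]; v2 <- t2[[mt]]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    s1 <- summarize_values(v1); s2 <- summarize_values(v2)
    rs <- rank_sum_test(v1, v2, method = "normal_approx")
    data.frame(feature = mt, n1 = s1$n, median1 = s1$median,
               lower1 = s1$lower_quartile, upper1 = s1$upper_quartile,
               n2 = s2$n, median2 = s2$median, lower2 = s2$lower_quartile,
               upper2 = s2$upper_quartile, rank_sum_p = rs$p_two_sided,
               stringsAsFactors = FALSE)
  }))
  comparison_table(rows, "topology", c(targets$label, nontargets$label))
}

feature_values_by_species <- function(value_fn, species) {
  out <- lapply(species, value_fn)
  names(out) <- species
  out
}

write_comparison_tsv <- function(ct, path, value_digits = 4L) {
  df <- as.data.frame(ct)
  num <- vapply(df, is.numeric, logical(1L))
  for (cn in names(df)[num]) {
    if (cn == "rank_sum_p") df[[cn]] <- signif(df[[cn]], 3L)
    else if (!cn %in% c("n1", "n2")) df[[cn]] <- round(df[[cn]], value_digits)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full gene-set conservation comparison
#'
#' Reads a study directory (real or written by [simulate_study()]),
#' derives the gene sets, and runs the four comparisons: per-species
#' dN/dS, per-species conservation scores, per-species ortholog
#' percentages, and network topology. Writes `table_dnds.tsv`,
#' `table_conservation.tsv`, `table_orthopct.tsv`,
#' `table_topology.tsv`, and `summary.json` (cross-species test
#' results, directional findings, and provenance) to `out_dir`.
#'
#' Expected inputs in `study_dir`: `targets.txt`, `orthologs.tsv`,
#' `ppi.tsv`; `families.tsv` (non-targets derived by family exclusion)
#' or `nontargets.txt`; and `seqs_<species>_human.fasta` /
#' `seqs_<species>_ortholog.fasta` for each species to be aligned.
#'
#' @param study_dir Input directory.
#' @param out_dir Report directory (created if needed).
#' @param species Species panel for the orthology features; default:
#'   every species present in the ortholog table.
#' @param alignment_species Species for the conservation-score stage;
#'   default: every species with both FASTA files present.
#' @param use_family_exclusion Derive the non-target set from
#'   `families.tsv` when present (the control-set construction);
#'   otherwise `nontargets.txt` is read as-is.
#' @param exact_cross_species Use the exact signed-rank distribution for
#'   the per-species-median cross-species tests instead of the default
#'   normal approximation.
#' @param cross_tie_correction Apply the tie variance correction in the
#'   cross-species normal approximation.
#' @param scheme [scoring_scheme()] for the alignment stage.
#' @return Invisibly, a list with the four `comparison_table`s and the
#'   summary list.
#' @export
run_all <- function(study_dir, out_dir,
                    species = NULL,
                    alignment_species = NULL,
                    use_family_exclusion = TRUE,
                    exact_cross_species = FALSE,
                    cross_tie_correction = FALSE,
                    scheme = scoring_scheme()) {
  need <- function(f) {
    p <- file.path(study_dir, f)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    p
  }
  targets <- read_gene_list(need("targets.txt"), label = "target")
  fam_path <- file.path(study_dir, "families.tsv")
  if (use_family_exclusion && file.exists(fam_path)) {
    nontargets <- derive_nontargets(targets, read_family_map(fam_path))
  } else {
    nontargets <- read_gene_list(need("nontargets.txt"),
                                 label = "nontarget")
  }
  table <- read_ortholog_table(need("orthologs.tsv"))
  net <- read_edge_list(need("ppi.tsv"))
  species <- species %||% table_species(table)
  cross_method <- if (exact_cross_species) "exact" else "normal_approx"

  dnds <- compare_feature(
    feature_values_by_species(function(sp) list(
      evolutionary_rates(table, targets, sp)$omega,
      evolutionary_rates(table, nontargets, sp)$omega), species),
    feature = "dnds", labels = c(targets$label, nontargets$label),
    cross_method = cross_method,
    cross_tie_correction = cross_tie_correction)

  if (is.null(alignment_species)) {
    fa <- list.files(study_dir, pattern = "^seqs_.*_human\\.fasta$")
    alignment_species <- intersect(species,
                                   sub("^seqs_(.*)_human\\.fasta$", "\\1", fa))
  }
  conservation <- NULL
  if (length(alignment_species) > 0L) {
    score_lists <- feature_values_by_species(function(sp) {
      human <- read_fasta(file.path(study_dir,
                                    sprintf("seqs_%s_human.fasta", sp)))
      orth <- read_fasta(file.path(study_dir,
                                   sprintf("seqs_%s_ortholog.fasta", sp)))
      list(conservation_scores(human, orth, targets, sp, scheme)$score,
           conservation_scores(human, orth, nontargets, sp, scheme)$score)
    }, alignment_species)
    conservation <- compare_feature(
      score_lists, feature = "conservation_score",
      labels = c(targets$label, nontargets$label),
      cross_method = cross_method,
      cross_tie_correction = cross_tie_correction)
  }

  orthopct <- compare_ortholog_percentages(table, targets, nontargets,
                                           panel = species)
  topology <- compare_topology(net, targets, nontargets)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_comparison_tsv(dnds, file.path(out_dir, "table_dnds.tsv"), 4L)
  if (!is.null(conservation))
    write_comparison_tsv(conservation,
                         file.path(out_dir, "table_conservation.tsv"), 1L)
  write_comparison_tsv(orthopct, file.path(out_dir, "table_orthopct.tsv"), 2L)
  write_comparison_tsv(topology, file.path(out_dir, "table_topology.tsv"), 4L)

  cross_list <- function(ct) {
    if (is.null(ct)) return(NULL)
    cr <- cross_species_test(ct)
    if (is.null(cr)) NULL else unclass(cr)
  }
  manifest_path <- file.path(study_dir, "manifest.json")
  findings <- list(
    lower_dnds_in_targets =
      median(dnds$median1, na.rm = TRUE) < median(dnds$median2, na.rm = TRUE),
    higher_conservation_in_targets = if (is.null(conservation)) NA else
      median(conservation$median1, na.rm = TRUE) >
        median(conservation$median2, na.rm = TRUE),
    higher_ortholog_pct_in_targets =
      median(orthopct$pct1) > median(orthopct$pct2),
    tighter_topology_in_targets = all(
      topology$median1[topology$feature != "aspl"] >=
        topology$median2[topology$feature != "aspl"]) &&
      topology$median1[topology$feature == "aspl"] <=
        topology$median2[topology$feature == "aspl"]
  )
  summary <- list(
    cross_species = list(
      dnds = cross_list(dnds),
      conservation_score = cross_list(conservation),
      ortholog_percentage = cross_list(orthopct)
    ),
    topology_rank_sum_p = setNames(as.list(signif(topology$rank_sum_p, 3L)),
                                   topology$feature),
    findings = findings,
    provenance = list(
      package_version = as.character(utils::packageVersion("consurvey")),
      study_dir = normalizePath(study_dir),
      manifest_md5 = if (file.exists(manifest_path))
        unname(tools::md5sum(manifest_path)) else NULL,
      seed = if (file.exists(manifest_path))
        read_manifest(study_dir)$seed else NULL,
      species = species,
      alignment_species = alignment_species
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(dnds = dnds, conservation = conservation,
                 orthopct = orthopct, topology = topology,
                 summary = summary))
}
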
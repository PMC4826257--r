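#' Synthetic-study configuration
#'
#' Bundles every knob of the synthetic study generator. The defaults
#' describe the reference study conditions: 300 target and 900
#' non-target genes over the 21-species panel, group median dN/dS of
#' 0.10 (targets) versus 0.13 (non-targets), one-to-one ortholog
#' presence probabilities 0.9 versus 0.75, and network degree
#' propensities 3:1 in favour of targets.
#'
#' @param n_targets,n_nontargets Positive gene counts per group.
#' @param species Character vector of species codes (unique, drawn from
#'   [species_panel()]).
#' @param seed Master integer seed; every sub-generator derives its own
#'   stream from it, so e.g. changing the species list does not perturb
#'   the network draw.
#' @param omega_logmean_target,omega_logmean_nontarget Log-scale means
#'   of the per-(gene, species) dN/dS ratio; the group median omega is
#'   `exp()` of these.
#' @param omega_logsd Log-scale standard deviation of omega.
#' @param ortholog_prob_target,ortholog_prob_nontarget Per-species
#'   probabilities in \[0, 1\] that a gene has a one-to-one ortholog.
#' @param one2many_prob Probability that a gene without a one-to-one
#'   ortholog gets a one-to-many record instead.
#' @param missing_rate Fraction of emitted ortholog rows carrying a
#'   missing dN or dS (exercises the non-null filter).
#' @param ds_logmean,ds_logsd Log-normal parameters of the synonymous
#'   rate dS; dN is derived as `omega * dS` so the extracted ratio
#'   recovers omega exactly.
#' @param seq_len_range Integer `(min, max)` protein length in residues
#'   (`min >= 20`).
#' @param divergence_scale Multiplier mapping a pair's omega to its
#'   per-site substitution probability, clipped to \[0, 0.95\].
#' @param degree_weight_target,degree_weight_nontarget Positive
#'   expected-degree propensities of the Chung-Lu network draw.
#' @param mean_degree Target average degree of the network.
#' @param triad_prob Probability of closing one extra triangle at each
#'   target node (raises target clustering).
#' @param n_families Number of protein families.
#' @param family_overlap Fraction of non-target genes placed into a
#'   family that also contains a target (these must be excluded by
#'   [derive_nontargets()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_targets = 300L,
                       n_nontargets = 900L,
                       species = species_panel(),
                       seed = 1L,
                       omega_logmean_target = log(0.10),
                       omega_logmean_nontarget = log(0.13),
                       omega_logsd = 0.9,
                       ortholog_prob_target = 0.9,
                       ortholog_prob_nontarget = 0.75,
                       one2many_prob = 0.05,
                       missing_rate = 0.02,
                       ds_logmean = log(0.3),
                       ds_logsd = 0.5,
                       seq_len_range = c(80L, 200L),
                       divergence_scale = 1.0,
                       degree_weight_target = 3,
                       degree_weight_nontarget = 1,
                       mean_degree = 8,
                       triad_prob = 0.2,
                       n_families = 200L,
                       family_overlap = 0.1) {
  cfg <- list(
    n_targets = as.integer(n_targets),
    n_nontargets = as.integer(n_nontargets),
    species = as.character(species),
    seed = as.integer(seed),
    omega_logmean_target = omega_logmean_target,
    omega_logmean_nontarget = omega_logmean_nontarget,
    omega_logsd = omega_logsd,
    ortholog_prob_target = ortholog_prob_target,
    ortholog_prob_nontarget = ortholog_prob_nontarget,
    one2many_prob = one2many_prob,
    missing_rate = missing_rate,
    ds_logmean = ds_logmean,
    ds_logsd = ds_logsd,
    seq_len_range = as.integer(seq_len_range),
    divergence_scale = divergence_scale,
    degree_weight_target = degree_weight_target,
    degree_weight_nontarget = degree_weight_nontarget,
    mean_degree = mean_degree,
    triad_prob = triad_prob,
    n_families = as.integer(n_families),
    family_overlap = family_overlap
  )
  probs <- c("ortholog_prob_target", "ortholog_prob_nontarget",
             "one2many_prob", "missing_rate", "triad_prob",
             "family_overlap")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must lie in [0, 1]", call. = FALSE)
  if (cfg$n_targets < 1L || cfg$n_nontargets < 1L || cfg$n_families < 1L)
    stop("counts must be positive", call. = FALSE)
  if (length(cfg$species) == 0L || anyDuplicated(cfg$species))
    stop("species codes must be non-empty and unique", call. = FALSE)
  unknown <- setdiff(cfg$species, species_panel())
  if (length(unknown) > 0L)
    stop("unknown species code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(cfg$seq_len_range) != 2L || cfg$seq_len_range[1L] < 20L ||
      cfg$seq_len_range[1L] > cfg$seq_len_range[2L])
    stop("seq_len_range must be (min, max) with min >= 20", call. = FALSE)
  if (cfg$omega_logsd <= 0 || cfg$ds_logsd <= 0)
    stop("log-scale sds must be positive", call. = FALSE)
  if (cfg$degree_weight_target <= 0 || cfg$degree_weight_nontarget <= 0 ||
      cfg$mean_degree <= 0 || cfg$divergence_scale < 0)
    stop("degree weights and mean degree must be positive, ",
         "divergence_scale non-negative", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d targets / %d non-targets, %d species, seed %d\n",
              x$n_targets, x$n_nontargets, length(x$species), x$seed))
  invisible(x)
}

sim_gene_ids <- function(config) {
  list(target = sprintf("T%04d", seq_len(config$n_targets)),
       nontarget = sprintf("N%04d", seq_len(config$n_nontargets)))
}

#' Simulate an ortholog table with planted group effects
#'
#' For every gene and species, with the group's presence probability a
#' one-to-one record is emitted whose dS is log-normal and whose dN is
#' `omega * dS`, with `omega` log-normal at the group's log-mean (so the
#' recovered dN/dS ratio equals the planted omega exactly); otherwise,
#' with probability `one2many_prob`, a one-to-many record is emitted. A
#' `missing_rate` fraction of emitted rows has its dN or dS blanked.
#'
#' @param config A [sim_config()].
#' @return An [ortholog_table()]; the planted per-row omega is attached
#'   as the `"sim_omega"` attribute (NA for one-to-many rows).
#' @export
simulate_orthology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  with_stream(config$seed, 1L, {
    grids <- lapply(c(target = "target", nontarget = "nontarget"),
                    function(grp) {
      expand.grid(human_gene = ids[[grp]], species = config$species,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    })
    grid <- rbind(grids$target, grids$nontarget)
    grp <- rep(c("target", "nontarget"),
               c(nrow(grids$target), nrow(grids$nontarget)))
    p_one2one <- ifelse(grp == "target", config$ortholog_prob_target,
                        config$ortholog_prob_nontarget)
    u <- runif(nrow(grid))
    is_one2one <- u < p_one2one
    is_one2many <- !is_one2one &
      (u - p_one2one) / pmax(1 - p_one2one, .Machine$double.eps) <
        config$one2many_prob
    keep <- is_one2one | is_one2many
    logmean <- ifelse(grp == "target", config$omega_logmean_target,
                      config$omega_logmean_nontarget)
    omega <- rlnorm(nrow(grid), meanlog = logmean, sdlog = config$omega_logsd)
    ds <- rlnorm(nrow(grid), meanlog = config$ds_logmean,
                 sdlog = config$ds_logsd)
    dn <- omega * ds
    tab <- data.frame(
      human_gene = grid$human_gene[keep],
      species = grid$species[keep],
      ortholog_gene = paste(grid$species[keep], grid$human_gene[keep],
                            sep = "_"),
      homology_type = ifelse(is_one2one[keep], "ortholog_one2one",
                             "ortholog_one2many"),
      dn = dn[keep],
      ds = ds[keep],
      stringsAsFactors = FALSE
    )
    miss <- runif(nrow(tab)) < config$missing_rate
    which_field <- runif(nrow(tab)) < 0.5
    tab$dn[miss & which_field] <- NA_real_
    tab$ds[miss & !which_field] <- NA_real_
    ord <- order(tab$human_gene, tab$species)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    out <- ortholog_table(tab)
    attr(out, "sim_omega") <- ifelse(tab$homology_type == "ortholog_one2one",
                                     omega[keep][ord], NA_real_)
    out
  })
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET[1:20], len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, p_sub) {
  res <- strsplit(seq, "")[[1L]]
  hit <- runif(length(res)) < p_sub
  if (any(hit)) {
    res[hit] <- vapply(res[hit], function(x)
      sample(setdiff(AA_ALPHABET[1:20], x), 1L), character(1L))
  }
  paste(res, collapse = "")
}

#' Simulate paired protein sequences for the one-to-one orthologs
#'
#' Each gene gets one random human protein with length uniform in
#' `seq_len_range`; for every one-to-one ortholog record the species
#' sequence is the human sequence with each site independently
#' substituted (uniformly among the 19 other residues) with probability
#' `min(0.95, divergence_scale * omega)`, so conservation scores degrade
#' with the planted evolutionary rate. Pairs exist only where
#' one-to-one records exist.
#'
#' @param config A [sim_config()].
#' @param table An ortholog table over `config`'s species, normally from
#'   [simulate_orthology()] (whose planted omegas are then used; for a
#'   foreign table the dN/dS ratio is used, with the median ratio
#'   substituted where dN or dS is missing).
#' @param species Species to generate pairs for (default: all of
#'   `config$species`). Each species uses its own RNG stream.
#' @return Named list per species, each with elements `human` and
#'   `ortholog`: named character vectors keyed by human gene id.
#' @export
simulate_sequences <- function(config, table, species = config$species) {
  stopifnot(inherits(config, "sim_config"),
            inherits(table, "ortholog_table"))
  unknown_sp <- setdiff(species, config$species)
  if (length(unknown_sp) > 0L)
    stop("unknown species code(s): ", paste(unknown_sp, collapse = ", "),
         call. = FALSE)
  ids <- sim_gene_ids(config)
  all_genes <- c(ids$target, ids$nontarget)
  if (!all(table$human_gene %in% all_genes))
    stop("ortholog table references gene(s) outside the configured study",
         call. = FALSE)
  human <- with_stream(config$seed, 2L, {
    # sample.int avoids sample()'s scalar expansion when min == max
    span <- config$seq_len_range[2L] - config$seq_len_range[1L] + 1L
    lens <- config$seq_len_range[1L] +
      sample.int(span, length(all_genes), replace = TRUE) - 1L
    setNames(vapply(lens, random_protein, character(1L)), all_genes)
  })
  omega <- attr(table, "sim_omega")
  if (is.null(omega)) {
    omega <- table$dn / table$ds
    omega[!is.finite(omega)] <- NA_real_
    omega[is.na(omega)] <- median(omega, na.rm = TRUE)
  }
  out <- list()
  for (sp in species) {
    sel <- table$species == sp & table$homology_type == "ortholog_one2one"
    genes <- table$human_gene[sel]
    om <- omega[sel]
    om[is.na(om)] <- exp(config$omega_logmean_nontarget)
    p_sub <- pmin(0.95, config$divergence_scale * om)
    orth <- with_stream(config$seed, 200L + match(sp, config$species), {
      setNames(mapply(function(g, p) mutate_protein(human[[g]], p),
                      genes, p_sub), genes)
    })
    out[[sp]] <- list(human = human[genes], ortholog = orth)
  }
  out
}

#' Simulate a protein-protein interaction network
#'
#' Chung-Lu style: node i receives weight
#' `w_i = mean_degree * propensity_i / mean(propensity)` and each
#' unordered pair (i, j) becomes an edge independently with probability
#' `min(1, w_i w_j / sum(w))`, giving expected degrees proportional to
#' the group propensities; no self-loops or duplicate edges arise by
#' construction. Afterwards, each target node closes one triangle among
#' two of its random neighbours with probability `triad_prob`, raising
#' target clustering coefficients.
#'
#' @param config A [sim_config()].
#' @return An undirected simple igraph whose vertices are all study
#'   genes (isolated genes included).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  nodes <- c(ids$target, ids$nontarget)
  n <- length(nodes)
  prop <- c(rep(config$degree_weight_target, config$n_targets),
            rep(config$degree_weight_nontarget, config$n_nontargets))
  w <- config$mean_degree * prop / mean(prop)
  S <- sum(w)
  with_stream(config$seed, 3L, {
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L, from = 2L:n)
    p <- pmin(1, w[i] * w[j] / S)
    hit <- runif(length(p)) < p
    ei <- i[hit]; ej <- j[hit]
    # triad closure at target nodes
    adj <- vector("list", n)
    for (k in seq_along(ei)) {
      adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
      adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
    }
    extra_i <- integer(0); extra_j <- integer(0)
    for (v in seq_len(config$n_targets)) {
      if (runif(1L) >= config$triad_prob) next
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      pick <- sample(nb, 2L)
      extra_i <- c(extra_i, min(pick)); extra_j <- c(extra_j, max(pick))
    }
    ei <- c(ei, extra_i); ej <- c(ej, extra_j)
    key <- paste(pmin(ei, ej), pmax(ei, ej))
    keep <- !duplicated(key)
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[ei[keep]], to = nodes[ej[keep]],
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    g
  })
}

#' Simulate a gene-to-family map
#'
#' Target genes draw their families from a target-family pool and
#' non-targets from a disjoint pool, except that a `family_overlap`
#' fraction of non-targets is additionally placed into a target family
#' (so that [derive_nontargets()] must exclude them).
#'
#' @param config A [sim_config()].
#' @return A [family_map()] covering every study gene.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  fams <- sprintf("FAM%04d", seq_len(config$n_families))
  n_target_fams <- max(1L, min(config$n_families - 1L,
    round(config$n_families * config$n_targets /
            (config$n_targets + config$n_nontargets))))
  target_pool <- fams[seq_len(n_target_fams)]
  nontarget_pool <- fams[-seq_len(n_target_fams)]
  with_stream(config$seed, 4L, {
    tmap <- lapply(seq_len(config$n_targets), function(i)
      unique(sample(target_pool, sample(1:2, 1L), replace = TRUE)))
    names(tmap) <- ids$target
    overlap <- runif(config$n_nontargets) < config$family_overlap
    nmap <- lapply(seq_len(config$n_nontargets), function(i) {
      own <- unique(sample(nontarget_pool, sample(1:2, 1L), replace = TRUE))
      if (overlap[i]) c(sample(target_pool, 1L), own) else own
    })
    names(nmap) <- ids$nontarget
    family_map(c(tmap, nmap))
  })
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_orthology()], [simulate_sequences()],
#' [simulate_network()] and [simulate_families()] from one master seed
#' (one RNG stream each) and optionally writes the whole study to a
#' directory: `targets.txt`, `nontargets.txt`, `orthologs.tsv`,
#' `seqs_<species>_human.fasta` / `seqs_<species>_ortholog.fasta`,
#' `ppi.tsv`, `families.tsv`, and a `manifest.json` echoing the
#' configuration.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @param sequence_species Species for which to simulate sequence pairs;
#'   defaults to all configured species.
#' @return A list of class `synthetic_study` with elements
#'   `target_genes`, `nontarget_genes`, `family_map`, `ortholog_table`,
#'   `sequence_pairs`, `network`, `config`.
#' @export
simulate_study <- function(config, dir = NULL,
                           sequence_species = config$species) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  table <- simulate_orthology(config)
  seqs <- simulate_sequences(config, table, species = sequence_species)
  net <- simulate_network(config)
  fams <- simulate_families(config)
  study <- structure(list(
    target_genes = gene_set("target", ids$target),
    nontarget_genes = gene_set("nontarget", ids$nontarget),
    family_map = fams,
    ortholog_table = table,
    sequence_pairs = seqs,
    network = net,
    config = config
  ), class = "synthetic_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d targets / %d non-targets, ",
                     "%d ortholog rows, %d species with sequences, ",
                     "%d network edges\n"),
              length(x$target_genes), length(x$nontarget_genes),
              nrow(x$ortholog_table), length(x$sequence_pairs),
              igraph::ecount(x$network)))
  invisible(x)
}

#' Write a synthetic study to a directory
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(study$target_genes$genes, file.path(dir, "targets.txt"))
  writeLines(study$nontarget_genes$genes, file.path(dir, "nontargets.txt"))
  tab <- as.data.frame(study$ortholog_table)
  tab$dn <- ifelse(is.na(tab$dn), "", format(tab$dn, digits = 15,
                                             scientific = FALSE, trim = TRUE))
  tab$ds <- ifelse(is.na(tab$ds), "", format(tab$ds, digits = 15,
                                             scientific = FALSE, trim = TRUE))
  write.table(tab, file.path(dir, "orthologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (sp in names(study$sequence_pairs)) {
    pair <- study$sequence_pairs[[sp]]
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(pair$human),
      file.path(dir, sprintf("seqs_%s_human.fasta", sp)))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(pair$ortholog),
      file.path(dir, sprintf("seqs_%s_ortholog.fasta", sp)))
  }
  el <- igraph::as_edgelist(study$network)
  write.table(el, file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- study$family_map
  write.table(
    data.frame(gene = rep(names(fam), lengths(fam)),
               family_accession = unlist(fam, use.names = FALSE)),
    file.path(dir, "families.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(unclass(study$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study manifest back into a configuration
#'
#' @param dir Study directory containing `manifest.json`.
#' @return A [sim_config()] equal to the one the study was written with.
#' @export
read_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, raw)
}
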
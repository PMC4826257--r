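small_cfg <- function(...) {
  sim_config(n_targets = 15, n_nontargets = 30,
             species = c("mmus", "rnor", "btau"), seed = 101, ...)
}

test_that("configurations validate their invariants", {
  expect_error(sim_config(ortholog_prob_target = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_targets = 0), "positive")
  expect_error(sim_config(species = c("mmus", "mmus")), "unique")
  expect_error(sim_config(species = "dragon"), "unknown species")
  expect_error(sim_config(seq_len_range = c(5, 50)), "min >= 20")
})

test_that("the same seed reproduces the study byte for byte", {
  cfg <- small_cfg()
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(cfg, dir = d1)
  simulate_study(cfg, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
})

test_that("degenerate presence probability yields no one-to-one targets", {
  cfg <- small_cfg(ortholog_prob_target = 0)
  tab <- simulate_orthology(cfg)
  t_one2one <- tab$homology_type == "ortholog_one2one" &
    startsWith(tab$human_gene, "T")
  expect_equal(sum(t_one2one), 0L)
})

test_that("planted omega difference shows in nearly every species' medians", {
  cfg <- sim_config(seed = 202)  # defaults: 300/900 genes, 21 species
  tab <- simulate_orthology(cfg)
  targets <- gene_set("t", sprintf("T%04d", 1:300))
  nontargets <- gene_set("n", sprintf("N%04d", 1:900))
  won <- vapply(cfg$species, function(sp) {
    median(evolutionary_rates(tab, targets, sp)$omega) <
      median(evolutionary_rates(tab, nontargets, sp)$omega)
  }, logical(1))
  expect_gte(sum(won), 19L)
})

test_that("sequence divergence follows the planted substitution probability", {
  # zero divergence: orthologs identical to the human sequences
  cfg0 <- small_cfg(divergence_scale = 0)
  seqs0 <- simulate_sequences(cfg0, simulate_orthology(cfg0))
  for (sp in names(seqs0))
    expect_identical(seqs0[[sp]]$human, seqs0[[sp]]$ortholog)

  diff_frac <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # huge omega: per-site substitution probability capped at 0.95
  cfg_hot <- sim_config(n_targets = 30, n_nontargets = 5, species = "mmus",
                        seed = 55, omega_logmean_target = log(1000),
                        omega_logsd = 0.1, divergence_scale = 1,
                        seq_len_range = c(500L, 500L), missing_rate = 0)
  s <- simulate_sequences(cfg_hot, simulate_orthology(cfg_hot))
  tg <- grep("^T", names(s$mmus$human), value = TRUE)
  fr <- mapply(diff_frac, s$mmus$human[tg], s$mmus$ortholog[tg])
  sd3 <- 3 * sqrt(0.95 * 0.05 / 500)
  expect_true(all(abs(fr - 0.95) < sd3))

  # moderate omega: differing-site fraction ~ scale * omega within 3 sd
  cfg_mid <- sim_config(n_targets = 40, n_nontargets = 5, species = "mmus",
                        seed = 56, omega_logmean_target = log(0.2),
                        omega_logsd = 1e-8, divergence_scale = 0.8,
                        seq_len_range = c(500L, 500L), missing_rate = 0)
  s <- simulate_sequences(cfg_mid, simulate_orthology(cfg_mid))
  tg <- grep("^T", names(s$mmus$human), value = TRUE)
  fr <- mapply(diff_frac, s$mmus$human[tg], s$mmus$ortholog[tg])
  p <- 0.8 * 0.2
  expect_true(all(abs(fr - p) < 3 * sqrt(p * (1 - p) / 500)))
})

test_that("sequence simulation rejects foreign genes", {
  cfg <- small_cfg()
  tab <- simulate_orthology(cfg)
  tab2 <- as.data.frame(tab)
  tab2$human_gene[1] <- "ALIEN"
  expect_error(simulate_sequences(cfg, ortholog_table(tab2)),
               "outside the configured study")
})

test_that("simulated networks are simple with group-controlled degrees", {
  cfg <- sim_config(n_targets = 500, n_nontargets = 500, species = "mmus",
                    seed = 60, degree_weight_target = 1,
                    degree_weight_nontarget = 1)
  net <- simulate_network(cfg)
  expect_true(igraph::is_simple(net))
  deg <- node_degree(net)
  dt <- deg[sprintf("T%04d", 1:500)]
  dn <- deg[sprintf("N%04d", 1:500)]
  # equal weights: group mean degrees equal within 3 sd of the difference
  se <- sqrt(var(dt) / 500 + var(dn) / 500)
  expect_lt(abs(mean(dt) - mean(dn)), 3 * se)

  cfg31 <- sim_config(n_targets = 500, n_nontargets = 500, species = "mmus",
                      seed = 61, degree_weight_target = 3,
                      degree_weight_nontarget = 1)
  net31 <- simulate_network(cfg31)
  deg31 <- node_degree(net31)
  r <- rank_sum_test(deg31[sprintf("T%04d", 1:500)],
                     deg31[sprintf("N%04d", 1:500)],
                     method = "normal_approx")
  expect_gt(mean(deg31[sprintf("T%04d", 1:500)]),
            mean(deg31[sprintf("N%04d", 1:500)]))
  expect_lt(r$p_two_sided, 0.01)
})

test_that("family simulation respects pools and overlap", {
  cfg <- small_cfg()
  fam <- simulate_families(cfg)
  expect_true(all(lengths(fam) >= 1L))
  expect_setequal(names(fam), c(sprintf("T%04d", 1:15),
                                sprintf("N%04d", 1:30)))

  cfg_ov <- sim_config(n_targets = 300, n_nontargets = 900,
                       species = "mmus", seed = 71, family_overlap = 0.1)
  fam_ov <- simulate_families(cfg_ov)
  targets <- gene_set("t", sprintf("T%04d", 1:300))
  nt <- derive_nontargets(targets, fam_ov)
  excluded <- 900 - length(nt$genes)
  expect_lt(abs(excluded - 90), 3 * sqrt(900 * 0.1 * 0.9))
})

test_that("study composition bounds row counts and round-trips its manifest", {
  cfg <- sim_config(n_targets = 10, n_nontargets = 20,
                    species = c("mmus", "rnor", "btau"), seed = 33)
  d <- tempfile()
  study <- simulate_study(cfg, dir = d)
  expect_lte(nrow(study$ortholog_table), 90L)

  cfg2 <- read_manifest(d)
  expect_s3_class(cfg2, "sim_config")
  expect_equal(unclass(cfg2), unclass(cfg))

  # written files reload into equivalent objects
  tab <- read_ortholog_table(file.path(d, "orthologs.tsv"))
  expect_equal(nrow(tab), nrow(study$ortholog_table))
  net <- read_edge_list(file.path(d, "ppi.tsv"))
  expect_equal(igraph::ecount(net), igraph::ecount(study$network))
  h <- read_fasta(file.path(d, "seqs_mmus_human.fasta"))
  expect_equal(h, study$sequence_pairs$mmus$human)
})
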
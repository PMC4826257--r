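test_that("FASTA parsing follows standard semantics", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "MKV", ">g2", "MK", "VWY"), f)
  seqs <- read_fasta(f)
  expect_equal(seqs, c(g1 = "MKV", g2 = "MKVWY"))

  writeLines(c(">g1", "MKV", ">g1", "MKW"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">g1", "MK1V"), f)
  expect_error(read_fasta(f), "illegal")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("scoring scheme validates its invariants", {
  expect_error(scoring_scheme(gap_open = 5, gap_extend = 6), "gap_extend")
  expect_error(scoring_scheme(gap_open = 0), "gap_extend")
  m <- blosum62_matrix()
  expect_true(all(m == t(m)))
  expect_equal(m["A", "A"], 4L)
  expect_equal(unname(m["X", c("A", "W")]), c(0L, 0L))
  expect_equal(m["X", "X"], -1L)
  m2 <- m; m2["A", "R"] <- 99L
  expect_error(scoring_scheme(m2), "symmetric")
})

test_that("NCBI-format matrix files round-trip through read_score_matrix", {
  m <- blosum62_matrix()
  f <- tempfile()
  writeLines(c("# comment",
               paste(colnames(m), collapse = " "),
               apply(cbind(rownames(m), m), 1L,
                     paste, collapse = " ")), f)
  expect_equal(read_score_matrix(f), m)
})

test_that("local alignment scores match small worked cases", {
  expect_equal(local_alignment_score("AAAA", "AAAA"), 16L)
  expect_equal(local_alignment_score("W", "P"), 0L)
  # self score = sum of diagonal entries
  m <- blosum62_matrix()
  s <- "MKVWYACD"
  expect_equal(local_alignment_score(s, s),
               sum(m[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])]))
  # symmetry
  expect_equal(local_alignment_score("MKVWY", "MKAWY"),
               local_alignment_score("MKAWY", "MKVWY"))
  # a length-1 gap costs open + extend: AC vs ABC-type case
  expect_equal(local_alignment_score("MW", "MGW"),
               max(m["M", "M"] + m["W", "W"] - 12L,
                   m["M", "M"] + m["G", "W"],  # no-gap alternative
                   m["W", "W"]))
})

test_that("local alignment equals the exhaustive matching-enumeration oracle", {
  S <- blosum62_matrix()
  letters4 <- c("A", "R", "N", "D")
  set.seed(5)
  for (i in 1:60) {
    a <- paste(sample(letters4, sample(1:5, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(letters4, sample(1:5, 1), replace = TRUE),
               collapse = "")
    expect_equal(local_alignment_score(a, b), brute_local_score(a, b, S),
                 info = paste(a, b))
  }
})

test_that("local alignment agrees with Biostrings on longer pairs", {
  core <- blosum62_matrix()[1:20, 1:20]
  set.seed(6)
  for (i in 1:25) {
    a <- paste(sample(rownames(core), sample(20:60, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(rownames(core), sample(20:60, 1), replace = TRUE),
               collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = core,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(local_alignment_score(a, b), as.integer(ref))
  }
})

test_that("appending residues never decreases the local score", {
  set.seed(8)
  aa <- rownames(blosum62_matrix())[1:20]
  for (i in 1:10) {
    a <- paste(sample(aa, 15, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 15, replace = TRUE), collapse = "")
    ext <- paste(sample(aa, 5, replace = TRUE), collapse = "")
    expect_gte(local_alignment_score(paste0(a, ext), b),
               local_alignment_score(a, b))
  }
})

test_that("conservation scores behave on identical and partial inputs", {
  seqs <- c(g1 = "MKVWYACD", g2 = "GHILNPQR", g3 = "STVWYAAA")
  genes <- gene_set("grp", c("g1", "g2", "g3", "g4"))
  suppressMessages(
    rec <- conservation_scores(seqs, seqs, genes, "mmus"))
  self <- vapply(seqs, function(s) local_alignment_score(s, s), integer(1))
  expect_equal(rec$score, unname(self[rec$human_gene]))
  expect_equal(attr(rec, "omitted"), 1L)

  expect_error(conservation_scores(seqs, seqs[1:2], genes, "mmus"),
               "identifier sets differ")
})

test_that("mean conservation score decreases with planted divergence", {
  base <- sim_config(n_targets = 20, n_nontargets = 20,
                     species = "mmus", seed = 31,
                     divergence_scale = 0, missing_rate = 0)
  hot <- sim_config(n_targets = 20, n_nontargets = 20,
                    species = "mmus", seed = 31,
                    divergence_scale = 0.5, missing_rate = 0)
  tab <- simulate_orthology(base)
  s0 <- simulate_sequences(base, tab)
  s5 <- simulate_sequences(hot, simulate_orthology(hot))
  # divergence 0: ortholog sequences identical to human
  expect_identical(s0$mmus$human, s0$mmus$ortholog)
  score <- function(pair) {
    g <- gene_set("all", names(pair$human))
    mean(conservation_scores(pair$human, pair$ortholog, g, "mmus")$score)
  }
  expect_gt(score(s0$mmus), score(s5$mmus))
})
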
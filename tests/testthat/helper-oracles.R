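# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Local alignment score by exhaustive enumeration of all equal-size
# increasing index matchings between the two sequences (every gapped
# local alignment corresponds to one such matching; 251 matchings for a
# 5x5 pair). Affine gaps: a run of g skipped residues between two
# consecutive aligned pairs costs open + g * extend per sequence.
brute_local_score <- function(a, b, S, open = 11L, extend = 1L) {
  ra <- strsplit(a, "")[[1L]]
  rb <- strsplit(b, "")[[1L]]
  la <- length(ra); lb <- length(rb)
  best <- 0L
  gapcost <- function(idx) {
    g <- diff(idx) - 1L
    sum(ifelse(g > 0L, open + g * extend, 0L))
  }
  for (k in seq_len(min(la, lb))) {
    ia <- utils::combn(la, k, simplify = FALSE)
    ib <- utils::combn(lb, k, simplify = FALSE)
    for (i in ia) for (j in ib) {
      sc <- sum(S[cbind(ra[i], rb[j])]) - gapcost(i) - gapcost(j)
      if (sc > best) best <- sc
    }
  }
  best
}

# Normalized betweenness by shortest-path counting through adjacency
# matrix powers: sigma_ij = (A^d)_ij at d = dist(i, j), and the count
# through v is sigma_iv * sigma_vj when d(i,v) + d(v,j) = d(i,j).
brute_betweenness <- function(A) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  P <- diag(n)
  for (d in seq_len(n)) {
    P <- P %*% A
    new <- is.infinite(dist) & P > 0
    dist[new] <- d
    sigma[new] <- P[new]
  }
  bv <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || i == v || j == v) next
      if (is.infinite(dist[i, j])) next
      if (is.finite(dist[i, v]) && is.finite(dist[v, j]) &&
          dist[i, v] + dist[v, j] == dist[i, j])
        acc <- acc + sigma[i, v] * sigma[v, j] / sigma[i, j]
    }
    bv[v] <- acc / ((n - 1) * (n - 2))
  }
  bv
}

# Exact two-sided rank-sum p by enumerating all choose(n+m, n) group
# labelings of the pooled sample.
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); n <- length(x)
  r <- rank(pooled)
  combos <- utils::combn(N, n)
  sums <- apply(combos, 2L, function(idx) sum(r[idx]))
  w <- sum(r[seq_len(n)])
  min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign
# assignments of the |difference| ranks.
enum_signed_rank_p <- function(d, chunk = 2^16) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  total <- 2^n
  lo <- hi <- 0
  done <- 0
  while (done < total) {
    k <- min(chunk, total - done)
    codes <- done + seq_len(k) - 1
    bits <- matrix(0, nrow = n, ncol = k)
    rest <- codes
    for (b in seq_len(n)) {
      bits[b, ] <- rest %% 2
      rest <- rest %/% 2
    }
    wplus <- as.numeric(r %*% bits)
    lo <- lo + sum(wplus <= w)
    hi <- hi + sum(wplus >= w)
    done <- done + k
  }
  min(1, 2 * min(lo / total, hi / total))
}

# Small random simple undirected graph as an igraph with named nodes.
random_test_graph <- function(n, p = 0.25) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

make_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
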
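# Independent oracles used to cross-check the implementations. These are
# deliberately naive (quadratic DP, exhaustive enumeration, brute-force
# search) and share no code with the package internals.

# Local alignment score by full Gotoh dynamic programming. Affine gap cost
# for a gap of length L is open + L * ext (so the first gapped column costs
# open + ext).
sw_score_oracle <- function(s1, s2, mat, open = 11, ext = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)     # best ending in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)  # best ending in a gap in s2 (up)
  Y <- matrix(-Inf, n + 1, m + 1)  # best ending in a gap in s1 (left)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      sc <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(0, sc + max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# The BLOSUM62 matrix as shipped with Biostrings (20 standard letters).
blosum62_oracle <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[amino_acids(), amino_acids()]
}

# Exhaustive ordered hallmark search: does any combination of
# non-overlapping, strictly ordered matches of the five motifs exist?
# Recursive backtracking over all match positions of each motif.
hallmark_oracle <- function(seq) {
  motifs <- c("D[TS]G", "Y", "[AFILMV][AFILMV]G", "D[TS]G",
              "[AFILMV][AFILMV]G")
  lens <- c(3, 1, 3, 3, 3)
  starts <- lapply(motifs, function(m) {
    g <- gregexpr(m, seq)[[1]]
    if (g[1] == -1) integer(0) else as.integer(g)
  })
  recurse <- function(i, from) {
    if (i > 5) return(TRUE)
    for (s in starts[[i]]) {
      if (s >= from && recurse(i + 1, s + lens[i])) return(TRUE)
    }
    FALSE
  }
  recurse(1, 1)
}

# Exhaustive two-group ANOSIM: R statistic for every distinct assignment of
# n1 units to group 1, and the exact P = #{R* >= R_obs} / n_assignments.
anosim_exhaustive <- function(d, grouping) {
  grouping <- as.factor(grouping)
  n <- attr(d, "Size")
  r <- rank(as.vector(d))
  M <- n * (n - 1) / 2
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  stat <- function(g) {
    between <- g[pi_] != g[pj]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  n1 <- sum(grouping == levels(grouping)[1])
  sets <- utils::combn(n, n1)
  Rs <- apply(sets, 2, function(s) {
    g <- rep(2L, n); g[s] <- 1L
    stat(g)
  })
  obs <- stat(as.integer(grouping))
  list(R = obs, p = mean(Rs >= obs - 1e-12), all_R = Rs)
}

# Exhaustive two-group Kruskal-Wallis permutation P over all distinct
# assignments of n1 observations to group 1.
kw_exhaustive <- function(x, g) {
  g <- as.factor(g)
  N <- length(x)
  r <- rank(x)
  tt <- table(x)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  h_of <- function(idx1) {
    R1 <- sum(r[idx1]); R2 <- sum(r) - R1
    n1 <- length(idx1); n2 <- N - n1
    h <- 12 / (N * (N + 1)) * (R1^2 / n1 + R2^2 / n2) - 3 * (N + 1)
    h / C
  }
  idx_obs <- which(g == levels(g)[1])
  H_obs <- h_of(idx_obs)
  sets <- utils::combn(N, length(idx_obs))
  Hs <- apply(sets, 2, h_of)
  list(H = H_obs, p = mean(Hs >= H_obs - 1e-12))
}

# Percent identity of two equal-role sequences via a simple per-position
# comparison of their Biostrings global alignment (used only for the
# within/between family divergence check, where sequences are gap-free and
# equal length).
pairwise_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  stopifnot(length(a) == length(b))
  mean(a == b) * 100
}

random_seq <- function(len, freqs = NULL) {
  aa <- amino_acids()
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste0(sample(aa, len, replace = TRUE, prob = freqs), collapse = "")
}
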
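# Community-style statistics on count profiles, implemented from scratch:
# Bray-Curtis distances, ANOSIM, SIMPER and tie-corrected Kruskal-Wallis with
# Monte-Carlo permutation P values.

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`, bounded in `[0, 1]` for
#' non-negative vectors.
#'
#' @param x,y Equal-length non-negative numeric vectors, not both all-zero.
#' @return A single dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(2, 1), c(1, 1))
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(x - y)) / tot
}

#' Pairwise distance matrix over profile rows
#'
#' @param x A [count_matrix()] or a numeric matrix with row names.
#' @param metric `"braycurtis"` (default) or `"euclidean"`.
#' @param relativize Convert rows to percentages (row sum 100) before
#'   computing distances (default `FALSE`: raw counts).
#' @return A [stats::dist] with attributes `metric` and `relativize`.
#' @export
profile_dist <- function(x, metric = c("braycurtis", "euclidean"),
                         relativize = FALSE) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  storage.mode(m) <- "double"
  if (relativize) m <- sweep(m, 1, rowSums(m), "/") * 100
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- if (metric == "braycurtis") {
        bray_curtis(m[i, ], m[j, ])
      } else {
        sqrt(sum((m[i, ] - m[j, ])^2))
      }
    }
  }
  out <- stats::as.dist(d)
  attr(out, "metric") <- metric
  attr(out, "relativize") <- relativize
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances exceed
#' within-group distances. All `n(n-1)/2` pairwise distances are ranked with
#' mid-ranks on ties; the statistic is
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2`, bounded in `[-1, 1]`. The permutation P value shuffles
#' group labels and uses the `+1` convention,
#' `P = (1 + #permuted R >= observed R) / (n_perm + 1)`.
#'
#' @param x A [count_matrix()], numeric matrix, or precomputed
#'   [stats::dist].
#' @param grouping Group label per unit (taken from the count matrix when
#'   omitted). Every group must have >= 2 members.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param metric,relativize Passed to [profile_dist()] when `x` is not
#'   already a `dist`.
#' @return List of class `anosim_result`: `R`, `p_value`, `n_perm`, `seed`,
#'   `metric`, `perm_R` (the permuted statistics).
#' @export
#' @examples
#' m <- make_count_matrix(5, 5, c(a = 120, b = 60, c = 30),
#'                        effect = c(0.5, 1, 1), seed = 1)
#' anosim(m, n_perm = 199, seed = 1)
anosim <- function(x, grouping = NULL, n_perm = 9999, seed = NULL,
                   metric = "braycurtis", relativize = FALSE) {
  if (inherits(x, "count_matrix")) {
    if (is.null(grouping)) grouping <- x$group
    d <- profile_dist(x, metric, relativize)
  } else if (inherits(x, "dist")) {
    d <- x
    metric <- attr(x, "metric") %||% "precomputed"
  } else {
    d <- profile_dist(x, metric, relativize)
  }
  if (is.null(grouping)) stop("grouping is required")
  grouping <- as.factor(grouping)
  n <- attr(d, "Size")
  stopifnot(length(grouping) == n)
  if (nlevels(grouping) < 2) stop("need >= 2 groups")
  if (any(table(grouping) < 2)) {
    stop("every group needs >= 2 members (ANOSIM is undefined for ",
         "singleton groups)")
  }
  r <- rank(as.vector(d))              # mid-ranks on ties
  M <- n * (n - 1) / 2
  # as.vector(dist) enumerates pairs (1,2..n), (2,3..n), ...
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  stat <- function(g) {
    between <- g[pair_i] != g[pair_j]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  R_obs <- stat(grouping)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) stat(sample(grouping)), numeric(1))
  })
  p <- (1 + sum(perm_R >= R_obs)) / (n_perm + 1)
  structure(list(R = R_obs, p_value = p, n_perm = n_perm, seed = seed,
                 metric = metric, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM (%s): R = %.4f, P = %.4g (%d permutations)\n",
              x$metric, x$R, x$p_value, x$n_perm))
  invisible(x)
}

#' Similarity percentages (SIMPER)
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-category contributions. For each cross-group pair of units `(j, k)`
#' the contribution of category `i` is `|x_ij - x_ik| / sum_v(x_vj + x_vk)`;
#' contributions are averaged over all cross-group pairs and sum exactly to
#' the overall average dissimilarity. Categories are ranked by descending
#' contribution (ties broken lexicographically).
#'
#' @param x A [count_matrix()] or numeric matrix.
#' @param grouping Group label per unit (from the count matrix when
#'   omitted).
#' @param pair The two group labels to compare (default: first two levels).
#' @param relativize Row-percentage the matrix first (default `FALSE`).
#' @return Data frame of class `simper_result`: `variable`,
#'   `contribution_pct` (percentage points of dissimilarity),
#'   `contribution_rel` (share of the overall, percent), `cumulative_pct`;
#'   attribute `overall_pct` holds the overall average between-group
#'   dissimilarity in percent.
#' @export
#' @examples
#' m <- fungal_peptidase_counts()
#' s <- simper(m, pair = c("mesophilic", "thermophilic"))
#' attr(s, "overall_pct")
simper <- function(x, grouping = NULL, pair = NULL, relativize = FALSE) {
  if (inherits(x, "count_matrix")) {
    if (is.null(grouping)) grouping <- x$group
    m <- x$counts
  } else {
    m <- as.matrix(x)
  }
  storage.mode(m) <- "double"
  if (is.null(grouping)) stop("grouping is required")
  grouping <- as.character(grouping)
  if (is.null(pair)) pair <- unique(grouping)[1:2]
  if (relativize) m <- sweep(m, 1, rowSums(m), "/") * 100
  a <- which(grouping == pair[1])
  b <- which(grouping == pair[2])
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty: ", paste(pair, collapse = " vs "))
  }
  contrib <- numeric(ncol(m))
  for (j in a) {
    for (k in b) {
      denom <- sum(m[j, ] + m[k, ])
      contrib <- contrib + abs(m[j, ] - m[k, ]) / denom
    }
  }
  contrib <- contrib / (length(a) * length(b)) * 100
  overall <- sum(contrib)
  ord <- order(-contrib, colnames(m))
  out <- data.frame(variable = colnames(m)[ord],
                    contribution_pct = contrib[ord],
                    contribution_rel = contrib[ord] / overall * 100,
                    row.names = NULL)
  out$cumulative_pct <- cumsum(out$contribution_rel)
  attr(out, "overall_pct") <- overall
  attr(out, "pair") <- pair
  class(out) <- c("simper_result", "data.frame")
  out
}

#' Kruskal-Wallis rank-sum test with tie correction and permutation P
#'
#' The H statistic uses mid-ranks and the tie correction
#' `C = 1 - sum(t^3 - t) / (N^3 - N)`; `H = H_raw / C`. The chi-square P
#' value uses the survival function with `k - 1` degrees of freedom; an
#' optional Monte-Carlo permutation P shuffles group labels with the `+1`
#' convention. When all observations are identical, `H = 0` and `P = 1`.
#'
#' @param x Either a list of numeric vectors (one per group) or a numeric
#'   vector accompanied by `g`.
#' @param g Group labels when `x` is a vector.
#' @param n_perm Monte-Carlo permutations for `p_perm` (0 = skip).
#' @param seed RNG seed for the permutations.
#' @return List of class `kw_result`: `H`, `df`, `p_chi2`, `p_perm`,
#'   `n_perm`, `seed`, `n`.
#' @export
#' @examples
#' kruskal_wallis(list(meso = c(8, 5, 5, 6),
#'                     thermo = c(5, 3, 3, 4, 4, 5, 2, 3)),
#'                n_perm = 999, seed = 1)
kruskal_wallis <- function(x, g = NULL, n_perm = 0, seed = NULL) {
  if (is.list(x)) {
    g <- rep(seq_along(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  stopifnot(!is.null(g), length(g) == length(x))
  g <- as.factor(g)
  N <- length(x)
  k <- nlevels(g)
  if (k < 2 || N < 3) stop("need >= 2 groups and >= 3 observations")
  r <- rank(x)
  tie_tab <- table(x)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  h_of <- function(gg) {
    Ri <- rowsum(r, gg)
    ni <- tabulate(gg, nbins = k)
    h <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
    if (C == 0) 0 else h / C
  }
  H <- h_of(as.integer(g))
  p_chi2 <- if (C == 0) 1 else pchisq(H, df = k - 1, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (C == 0) {
      p_perm <- 1
    } else {
      gi <- as.integer(g)
      perm_H <- with_seed(seed, {
        vapply(seq_len(n_perm), function(i) h_of(sample(gi)), numeric(1))
      })
      p_perm <- (1 + sum(perm_H >= H - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(H = H, df = k - 1, p_chi2 = p_chi2, p_perm = p_perm,
                 n_perm = n_perm, seed = seed, n = N),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, P(chi2) = %.4g", x$H,
              x$df, x$p_chi2))
  if (!is.na(x$p_perm)) {
    cat(sprintf(", P(perm, %d draws) = %.4g", x$n_perm, x$p_perm))
  }
  cat("\n")
  invisible(x)
}

#' Two-group t-test (Welch, Student or paired)
#'
#' Thin wrapper around [stats::t.test()] returning a flat result with the
#' convention `diff = mean(y) - mean(x)`. Degenerate inputs are handled
#' explicitly: two constant, equal groups give `t = 0, P = 1`; a paired test
#' with zero variance of the differences is an error.
#'
#' @param x,y Numeric vectors (matched and equal-length for `mode =
#'   "paired"`).
#' @param mode `"welch"` (unequal variances, default), `"student"` (pooled)
#'   or `"paired"`.
#' @return List: `mean_x`, `mean_y`, `diff`, `t`, `df`, `p_value`, `mode`.
#' @export
#' @examples
#' t_test(c(1, 2, 3), c(4, 5, 6))
t_test <- function(x, y, mode = c("welch", "student", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired" && length(x) != length(y)) {
    stop("paired mode requires matched vectors of equal length")
  }
  out <- list(mean_x = mean(x), mean_y = mean(y),
              diff = mean(y) - mean(x), mode = mode)
  degenerate <- if (mode == "paired") sd(y - x) == 0 else
    sd(x) == 0 && sd(y) == 0
  if (is.na(degenerate)) degenerate <- FALSE
  if (degenerate) {
    if (mode == "paired") {
      stop("degenerate paired test: differences have zero variance")
    }
    if (out$diff == 0) {
      return(c(out, list(t = 0, df = NA_real_, p_value = 1)))
    }
    stop("degenerate test: both groups constant with unequal means")
  }
  tt <- t.test(y, x, paired = mode == "paired",
               var.equal = mode == "student")
  c(out, list(t = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
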
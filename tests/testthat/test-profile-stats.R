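# Bray-Curtis / ANOSIM / SIMPER / Kruskal-Wallis, cross-checked against
# hand formulas, exhaustive enumeration, and the vegan implementations.

test_that("Bray-Curtis matches hand evaluation and its bounds", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("profile distances agree with vegan::vegdist", {
  set.seed(3)
  m <- matrix(rpois(60, 30), 10, 6,
              dimnames = list(sprintf("s%d", 1:10), letters[1:6]))
  d <- profile_dist(m)
  dv <- vegan::vegdist(m, "bray")
  expect_equal(as.vector(d), as.vector(dv), tolerance = 1e-12)
  de <- profile_dist(m, "euclidean")
  expect_equal(as.vector(de), as.vector(stats::dist(m)), tolerance = 1e-12)
})

test_that("ANOSIM gives R = 1 under complete separation", {
  # two tight clusters: all between-distances exceed all within-distances
  m <- rbind(matrix(c(100, 2, 101, 3, 102, 2), 3, 2, byrow = TRUE),
             matrix(c(2, 100, 3, 101, 2, 102), 3, 2, byrow = TRUE))
  rownames(m) <- sprintf("u%d", 1:6); colnames(m) <- c("a", "b")
  a <- anosim(m, rep(c("g1", "g2"), each = 3), n_perm = 99, seed = 1)
  expect_equal(a$R, 1)
})

test_that("ANOSIM matches vegan and its exhaustive permutation oracle", {
  m <- make_count_matrix(4, 4, c(a = 120, b = 60, c = 30, d = 15),
                         effect = c(0.6, 1, 1.3, 1), seed = 5)
  a <- anosim(m, n_perm = 9999, seed = 11)
  av <- vegan::anosim(m$counts, m$group, permutations = 99,
                      distance = "bray")
  expect_equal(a$R, unname(av$statistic), tolerance = 1e-12)
  ex <- anosim_exhaustive(profile_dist(m), m$group)
  expect_equal(a$R, ex$R)
  # sampled P within Monte-Carlo error of the exact enumeration P
  mc_se <- sqrt(ex$p * (1 - ex$p) / 9999)
  expect_lt(abs(a$p_value - ex$p), 3 * mc_se + 2 / 9999)
})

test_that("ANOSIM validates groups and is invariant to row order", {
  m <- make_count_matrix(3, 3, c(a = 50, b = 20), seed = 2)
  expect_error(anosim(m$counts, c("g1", rep("g2", 5)), n_perm = 9),
               ">= 2 members")
  perm <- c(4, 1, 6, 2, 3, 5)
  a1 <- anosim(m$counts, m$group, n_perm = 499, seed = 7)
  a2 <- anosim(m$counts[perm, ], m$group[perm], n_perm = 499, seed = 7)
  expect_equal(a1$R, a2$R)
})

test_that("SIMPER decomposes the single-pair dissimilarity exactly", {
  m <- rbind(s1 = c(A = 5, B = 3, C = 2), s2 = c(A = 1, B = 3, C = 6))
  s <- simper(m, c("g1", "g2"), pair = c("g1", "g2"))
  expect_equal(attr(s, "overall_pct"), bray_curtis(m[1, ], m[2, ]) * 100)
  expect_equal(sum(s$contribution_pct), attr(s, "overall_pct"))
  # hand: denom = 20; |diffs| = 4,0,4 -> contributions 20%,0%,20%
  expect_equal(sort(s$contribution_pct), c(0, 20, 20))
})

test_that("SIMPER contributions always sum to the overall dissimilarity", {
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1); k <- sample(2:8, 1)
    m <- matrix(rpois((n1 + n2) * k, 20), n1 + n2, k)
    m[1, ] <- m[1, ] + 1  # avoid all-zero row pairs
    rownames(m) <- sprintf("u%d", seq_len(n1 + n2))
    colnames(m) <- sprintf("v%d", seq_len(k))
    g <- rep(c("a", "b"), c(n1, n2))
    s <- simper(m, g, pair = c("a", "b"))
    expect_equal(sum(s$contribution_pct), attr(s, "overall_pct"),
                 tolerance = 1e-9)
    expect_equal(s$cumulative_pct[k], 100, tolerance = 1e-6)
    expect_false(is.unsorted(rev(s$contribution_pct)))
  }
})

test_that("SIMPER agrees with vegan's average contributions", {
  m <- make_count_matrix(4, 5, c(a = 150, b = 70, c = 40, d = 10),
                         effect = c(0.5, 1, 1, 2), seed = 9)
  s <- simper(m, pair = c("mesophilic", "thermophilic"))
  sv <- summary(vegan::simper(m$counts, m$group,
                              permutations = 0))$mesophilic_thermophilic
  expect_equal(s$contribution_pct[match(rownames(sv), s$variable)] / 100,
               unname(sv$average), tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches stats::kruskal.test with ties", {
  x <- c(8, 5, 5, 6, 5, 3, 3, 4, 4, 5, 2, 3)
  g <- rep(c("m", "t"), c(4, 8))
  k <- kruskal_wallis(x, g)
  ref <- stats::kruskal.test(x, factor(g))
  expect_equal(k$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(k$p_chi2, ref$p.value, tolerance = 1e-12)
  # chi-square survival agrees with an independent incomplete-gamma route
  p_gamma <- pracma::gammainc(k$H / 2, k$df / 2)[["uppinc"]] /
    gamma(k$df / 2)
  expect_equal(k$p_chi2, p_gamma, tolerance = 1e-10)
})

test_that("Kruskal-Wallis is rank-invariant and handles degeneracy", {
  k1 <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  k2 <- kruskal_wallis(list(c(10, 20), c(30, 40)))
  expect_equal(k1$H, k2$H)
  kc <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)), n_perm = 99, seed = 1)
  expect_equal(kc$H, 0)
  expect_equal(kc$p_chi2, 1)
  expect_equal(kc$p_perm, 1)
})

test_that("three singleton groups reach the enumerable maximum H", {
  # N = 3, all distinct: every assignment is a relabelling, H is constant
  # and equals its maximum 2 (chi-square H for a perfect 3-way split)
  k <- kruskal_wallis(list(1, 2, 3))
  sets <- combinat_perms <- NULL
  Hs <- apply(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                    c(3, 1, 2), c(3, 2, 1)), 1, function(p) {
    kruskal_wallis(split(c(1, 2, 3)[p], 1:3))$H
  })
  expect_equal(k$H, max(Hs))
  expect_equal(k$H, 2)
})

test_that("Monte-Carlo permutation P tracks the exhaustive enumeration", {
  x <- c(3, 7, 4, 9, 6, 2, 8, 5, 5, 1)
  g <- rep(c("a", "b"), each = 5)
  ex <- kw_exhaustive(x, g)
  k <- kruskal_wallis(x, g, n_perm = 20000, seed = 3)
  mc_se <- sqrt(ex$p * (1 - ex$p) / 20000)
  expect_lt(abs(k$p_perm - ex$p), 3 * mc_se + 2 / 20000)
})

test_that("permutation results are reproducible given the seed", {
  m <- make_count_matrix(4, 4, c(a = 80, b = 40), effect = c(0.7, 1),
                         seed = 6)
  a1 <- anosim(m, n_perm = 999, seed = 42)
  a2 <- anosim(m, n_perm = 999, seed = 42)
  expect_identical(a1$p_value, a2$p_value)
  k1 <- kruskal_wallis(list(c(1, 5, 3), c(2, 8, 9)), n_perm = 999,
                       seed = 42)
  k2 <- kruskal_wallis(list(c(1, 5, 3), c(2, 8, 9)), n_perm = 999,
                       seed = 42)
  expect_identical(k1$p_perm, k2$p_perm)
})
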
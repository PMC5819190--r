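# Peptidase mining: k-mer index, best-hit classification, profiling.

# reference_library with hand-chosen sequences, for exact index checks
fixed_reference <- function(seqs, families) {
  ids <- sprintf("SYN%06d", seq_along(seqs))
  sset <- Biostrings::AAStringSet(seqs)
  names(sset) <- sprintf("%s|FAM=%s|TYPE=%s", ids, families,
                         substr(families, 1, 1))
  structure(list(
    sequences = sset,
    info = data.frame(id = ids, family = families,
                      catalytic_type = family_to_catalytic_type(families))
  ), class = "reference_library")
}

test_that("k-mer index postings match hand enumeration", {
  ref <- fixed_reference("ACDEF", "A01")
  idx <- build_kmer_index(ref, k = 3)
  expect_equal(idx$n_postings, 3L)
  expect_setequal(ls(idx$postings), c("ACD", "CDE", "DEF"))
  expect_equal(idx$postings[["CDE"]], 1L)
  expect_error(build_kmer_index(ref, k = 2), "3..6")
})

test_that("identical entries are both retrievable from any shared k-mer", {
  ref <- fixed_reference(c("MKLVACDEFGHIK", "MKLVACDEFGHIK"),
                         c("A01", "A01"))
  idx <- build_kmer_index(ref, k = 4)
  expect_setequal(idx$postings[["MKLV"]], c(1L, 2L))
  expect_setequal(idx$postings[["FGHI"]], c(1L, 2L))
})

test_that("every entry of a random library is retrievable via its k-mers", {
  ref <- make_reference_library(
    data.frame(code = sprintf("S%02d", 1:20), n = 5, length = 120),
    seed = 13)
  idx <- build_kmer_index(ref, k = 4)
  seqs <- as.character(ref$sequences)
  for (i in seq_along(seqs)) {
    kms <- thermopep:::seq_kmers(seqs[i], 4)
    hit <- any(vapply(kms, function(km) i %in% idx$postings[[km]],
                      logical(1)))
    expect_true(hit)
  }
})

test_that("catalytic type mapping covers all nine letters and rejects others", {
  expect_equal(family_to_catalytic_type("A01"), "Aspartic")
  expect_equal(family_to_catalytic_type("P01"), "Mixed")
  expect_equal(family_to_catalytic_type("U00"), "Unknown")
  expect_equal(
    family_to_catalytic_type(c("S08", "C14", "M28", "T01", "G01", "N01")),
    c("Serine", "Cysteine", "Metallo", "Threonine", "Glutamic",
      "Asparagine"))
  expect_error(family_to_catalytic_type("X99"), "X99")
  expect_error(family_to_catalytic_type(""), "empty")
})

test_that("self-hit classifies to the true family at identity 100", {
  ref <- make_reference_library(
    data.frame(code = c("A01", "S08"), n = 3, length = c(300, 320)),
    seed = 1)
  idx <- build_kmer_index(ref)
  ann <- classify_protein(as.character(ref$sequences[[1]]), idx,
                          query_id = "self")
  expect_equal(ann$status, "hit")
  expect_equal(ann$family, "A01")
  expect_equal(ann$catalytic_type, "Aspartic")
  expect_equal(ann$identity, 100)
  expect_equal(ann$coverage, 1)
})

test_that("too-short queries and random queries yield no-calls", {
  ref <- make_reference_library(
    data.frame(code = c("A01", "S08"), n = 3, length = c(300, 400)),
    seed = 1)
  idx <- build_kmer_index(ref)
  expect_equal(classify_protein("MK", idx)$reason, "too short")
  # 100 random queries at default thresholds: no-call rate >= 99%
  set.seed(404)
  calls <- vapply(1:100, function(i) {
    classify_protein(random_seq(400), idx)$status
  }, character(1))
  expect_gte(sum(calls == "no_call"), 99)
})

test_that("mutated reference members are recovered at their true family", {
  ref <- make_reference_library(
    data.frame(code = c("A01", "S08", "M28"), n = 4,
               length = c(300, 350, 320)), seed = 21)
  idx <- build_kmer_index(ref)
  set.seed(22)
  n_trials <- 200
  correct <- 0
  for (i in seq_len(n_trials)) {
    j <- sample(nrow(ref$info), 1)
    q <- thermopep:::mutate_protein(as.character(ref$sequences[[j]]), 0.1)
    ann <- classify_protein(q, idx)
    if (ann$status == "hit" && ann$family == ref$info$family[j]) {
      correct <- correct + 1
    }
  }
  expect_gte(correct / n_trials, 0.95)
})

test_that("classification is deterministic given query, reference, params", {
  ref <- make_reference_library(
    data.frame(code = c("A01", "A02"), n = 3, length = 250), seed = 31)
  idx <- build_kmer_index(ref)
  q <- thermopep:::mutate_protein(as.character(ref$sequences[[2]]), 0.05)
  a1 <- classify_protein(q, idx)
  a2 <- classify_protein(q, idx)
  expect_identical(a1, a2)
})

test_that("species profiling counts hits and preserves row sums", {
  ann <- data.frame(
    query_id = sprintf("q%d", 1:6),
    status = c(rep("hit", 5), "no_call"),
    family = c("A01", "A01", "A01", "S08", "S08", NA),
    catalytic_type = c(rep("Aspartic", 3), rep("Serine", 2), NA),
    species = "sp1", group = "mesophilic")
  m_type <- profile_species(ann, level = "catalytic_type")
  expect_equal(unname(m_type$counts["sp1", c("Aspartic", "Serine")]),
               c(3L, 2L))
  expect_equal(sum(m_type$counts), 5L)
  m_fam <- profile_species(ann, level = "family")
  expect_equal(unname(m_fam$counts["sp1", c("A01", "S08")]), c(3L, 2L))
  expect_equal(rowSums(m_fam$counts), rowSums(m_type$counts))
  # species with zero annotations appear as an all-zero row
  m0 <- profile_species(ann, species_levels = c("sp1", "sp_empty"))
  expect_equal(sum(m0$counts["sp_empty", ]), 0L)
})

test_that("mining a zero-mutation synthetic proteome recovers truth counts", {
  ref <- make_reference_library(
    data.frame(code = c("A01", "S08"), n = 3, length = c(250, 280)),
    seed = 41)
  idx <- build_kmer_index(ref)
  reg <- proteome_regime(n_proteins = 40, peptidase_fraction = 0.25,
                         mutation_rate = 0, seed = 42)
  p <- make_proteome(reg, ref, species_id = "spT", group = "thermophilic")
  ann <- mine_proteome(p$sequences, idx, species = "spT",
                       group = "thermophilic")
  truth_counts <- table(p$truth$family[p$truth$class == "peptidase"])
  m <- profile_species(ann, level = "family")
  for (fam in names(truth_counts)) {
    expect_equal(unname(m$counts["spT", fam]),
                 as.integer(truth_counts[[fam]]))
  }
  expect_equal(sum(m$counts), sum(truth_counts))
})

test_that("Smith-Waterman rescoring matches the quadratic DP oracle", {
  mat <- blosum62_oracle()
  set.seed(77)
  for (i in 1:12) {
    s1 <- random_seq(sample(10:50, 1))
    s2 <- random_seq(sample(10:50, 1))
    ref <- fixed_reference(s2, "A01")
    got <- thermopep:::sw_rescore(s1, ref$sequences)$score
    expect_equal(got, sw_score_oracle(s1, s2, mat))
  }
})

test_that("non-standard residues score zero and do not break alignment", {
  ref <- fixed_reference("MKWVFDEQRHLCYNGGARTS", "A01")
  idx <- build_kmer_index(ref, k = 4)
  # X runs score 0: appending them must not change the SW score
  base <- thermopep:::sw_rescore("MKWVFDEQRHLCYNGGARTS",
                                 ref$sequences)$score
  with_x <- thermopep:::sw_rescore("MKWVFDEQRHLCYNGGARTSXXXX",
                                   ref$sequences)$score
  expect_equal(base, with_x)
})
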
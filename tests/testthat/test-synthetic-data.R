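# Ground-truth generators: reference libraries, proteomes, count matrices,
# hallmark sets.

test_that("reference library construction respects family specs", {
  ref <- make_reference_library(data.frame(code = "A01", n = 3,
                                           length = 350), seed = 1)
  expect_equal(nrow(ref$info), 3)
  expect_true(all(ref$info$family == "A01"))
  expect_true(all(ref$info$catalytic_type == "Aspartic"))
  expect_true(all(Biostrings::width(ref$sequences) == 350))
  expect_match(names(ref$sequences)[1], "^SYN000001\\|FAM=A01\\|TYPE=A$")
})

test_that("empty family list gives an empty library that cannot be indexed", {
  ref <- make_reference_library(data.frame(code = character(0),
                                           n = integer(0),
                                           length = integer(0)))
  expect_equal(length(ref$sequences), 0)
  expect_error(build_kmer_index(ref), "empty reference")
})

test_that("malformed family codes are rejected by name", {
  expect_error(
    make_reference_library(data.frame(code = c("A01", "x9"), n = 1,
                                      length = 100)),
    "x9")
})

test_that("within-family identity exceeds between-family identity", {
  ref <- make_reference_library(
    data.frame(code = c("A01", "S08"), n = 5, length = 300), seed = 7)
  seqs <- as.character(ref$sequences)
  fam <- ref$info$family
  ids <- utils::combn(length(seqs), 2)
  pid <- apply(ids, 2, function(p) pairwise_identity(seqs[p[1]], seqs[p[2]]))
  same <- fam[ids[1, ]] == fam[ids[2, ]]
  expect_gt(mean(pid[same]), mean(pid[!same]))
  expect_gt(mean(pid[same]), 90)   # <= 10% within-family divergence
  # unrelated ancestors: between-family identity near random expectation
  expect_lt(mean(pid[!same]), 20)
})

test_that("proteome generation partitions records into an exact truth table", {
  ref <- make_reference_library(data.frame(code = "A01", n = 3,
                                           length = 200), seed = 1)
  reg <- proteome_regime(n_proteins = 50, peptidase_fraction = 0.2,
                         seed = 11)
  p <- make_proteome(reg, ref, species_id = "spX", group = "thermophilic")
  expect_equal(length(p$sequences), 50)
  expect_equal(nrow(p$truth), 50)
  expect_equal(anyDuplicated(p$truth$id), 0)
  expect_setequal(p$truth$id, names(p$sequences))
  expect_equal(sum(p$truth$class == "peptidase"), floor(50 * 0.2))
  expect_true(all(is.na(p$truth$family[p$truth$class == "background"])))
})

test_that("zero peptidase fraction needs no reference; positive does", {
  reg0 <- proteome_regime(n_proteins = 30, peptidase_fraction = 0, seed = 2)
  p <- make_proteome(reg0, species_id = "s", group = "mesophilic")
  expect_equal(sum(p$truth$class == "peptidase"), 0)
  regp <- proteome_regime(n_proteins = 30, peptidase_fraction = 0.5,
                          seed = 2)
  expect_error(make_proteome(regp, species_id = "s", group = "mesophilic"),
               "non-empty reference")
})

test_that("proteome generation is byte-reproducible given the regime", {
  reg <- proteome_regime(n_proteins = 25, seed = 99)
  p1 <- make_proteome(reg, species_id = "s", group = "g")
  p2 <- make_proteome(reg, species_id = "s", group = "g")
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(p1$sequences, f1)
  Biostrings::writeXStringSet(p2$sequences, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("regime validation enforces the frequency-vector invariants", {
  bad <- aa_background_freqs(); bad["A"] <- bad["A"] + 0.01
  expect_error(proteome_regime(10, baseline_freqs = bad), "sum to 1")
  expect_error(proteome_regime(10, peptidase_fraction = 1.5), "\\[0, 1\\]")
  # shifted law is clipped at zero and renormalized
  s <- setNames(numeric(20), amino_acids()); s["W"] <- -1
  reg <- proteome_regime(10, shift = s)
  expect_equal(sum(reg$shifted_freqs), 1, tolerance = 1e-12)
  expect_equal(unname(reg$shifted_freqs["W"]), 0)
})

test_that("background residues follow the shifted law", {
  # empirical frequencies at ~5e5 residues reflect the thermophilic shift:
  # every raised residue above baseline, every lowered residue below
  reg <- proteome_regime(n_proteins = 1250, shift = thermophilic_shift(),
                         seed = 5)
  p <- make_proteome(reg, species_id = "s", group = "g")
  freq <- colSums(Biostrings::alphabetFrequency(p$sequences)[,
                                                             amino_acids()])
  freq <- freq / sum(freq)
  base <- aa_background_freqs()
  up <- c("A", "E", "G", "P", "R", "V")
  down <- c("C", "H", "I", "K", "M", "N", "Q", "S", "T", "W")
  expect_true(all(freq[up] > base[up]))
  expect_true(all(freq[down] < base[down]))
  expect_gt(sum(Biostrings::width(p$sequences)), 4e5)
  # goodness of fit against the generating law not rejected in most seeds
  pvals <- vapply(1:6, function(sd) {
    regi <- proteome_regime(n_proteins = 300, seed = sd)
    pi <- make_proteome(regi, species_id = "s", group = "g")
    counts <- colSums(Biostrings::alphabetFrequency(pi$sequences)[,
                                                            amino_acids()])
    suppressWarnings(
      stats::chisq.test(counts, p = regi$shifted_freqs)$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 5)
})

test_that("reference headers parse in both dialects and round-trip FASTA", {
  r <- parse_reference_headers(
    c("SYN000001|FAM=A01|TYPE=A", "SYN000002|FAM=S08A|TYPE=S"))
  expect_equal(r$family, c("A01", "S08A"))
  expect_equal(r$catalytic_type, c("Aspartic", "Serine"))
  m <- parse_reference_headers(
    "MER0000101 pepsin A (Homo sapiens) [A01.001]#A01.001#", "merops")
  expect_equal(m$family, "A01")
  expect_error(parse_reference_headers("no_annotation_here"), "parse")
  ref <- make_reference_library(data.frame(code = "M28", n = 2,
                                           length = 60), seed = 3)
  f <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(ref$sequences, f)
  back <- read_reference_fasta(f)
  expect_equal(back$info, ref$info)
  expect_equal(as.character(back$sequences), as.character(ref$sequences),
               ignore_attr = TRUE)
})

test_that("count matrix simulation: Poisson limit and group structure", {
  m <- make_count_matrix(200, 2, c(cat = 50), dispersion = 0, seed = 3)
  g1 <- m$counts[m$group == "mesophilic", 1]
  expect_equal(stats::var(g1) / mean(g1), 1, tolerance = 0.25)
  expect_error(make_count_matrix(0, 3, c(a = 5)), ">= 1")
  expect_error(make_count_matrix(3, 3, c(a = -5)), "positive")
  m2 <- make_count_matrix(3, 4, c(a = 100, b = 50), effect = c(0.5, 1),
                          seed = 1)
  expect_equal(as.vector(table(m2$group)[c("mesophilic", "thermophilic")]),
               c(3L, 4L))
  expect_equal(attr(m2, "truth")$effect[["a"]], 0.5)
})

test_that("hallmark set generation is labelled and reproducible", {
  h1 <- make_hallmark_set(4, 6, seed = 10)
  h2 <- make_hallmark_set(4, 6, seed = 10)
  expect_identical(as.character(h1$sequences), as.character(h2$sequences))
  expect_equal(sum(h1$truth$functional), 4)
  expect_equal(nrow(h1$truth), 10)
})
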
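# Synthetic sequence data with recorded ground truth: annotated reference
# libraries, whole proteomes, and hallmark-labelled aspartic-peptidase sets.

#' Describe the generative regime of a synthetic proteome
#'
#' A regime bundles everything [make_proteome()] needs: the background
#' amino-acid law, an additive compositional shift (the thermophilic signal),
#' the protein count and length law, the fraction of proteins derived from a
#' peptidase reference library, and the RNG seed.
#'
#' Background proteins are i.i.d. residue draws from the shifted law — there
#' is no positional structure, which is sufficient for compositional
#' statistics but not for motif- or domain-level realism. Protein lengths are
#' log-normal (default median 400 residues) to mimic the long right tail of
#' real proteome length distributions.
#'
#' @param n_proteins Number of proteins to generate.
#' @param shift Signed additive frequency deltas over [amino_acids()];
#'   applied to `baseline_freqs`, clipped at zero and renormalized. Default:
#'   no shift. Use [thermophilic_shift()] for the thermophilic regime.
#' @param baseline_freqs Background amino-acid probabilities, summing to 1.
#' @param length_meanlog,length_sdlog Log-normal parameters of protein length
#'   (default median `exp(meanlog)` = 400 residues, sigma 0.45).
#' @param peptidase_fraction Proportion of proteins in `[0, 1]` drawn as
#'   mutated copies of reference peptidases rather than background draws.
#' @param mutation_rate Per-residue substitution probability applied to
#'   reference-derived peptidases (uniform over the 19 alternatives, no
#'   indels).
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   regime.
#' @return An object of class `proteome_regime`.
#' @seealso [make_proteome()]
#' @export
#' @examples
#' proteome_regime(n_proteins = 100, shift = thermophilic_shift(), seed = 1)
proteome_regime <- function(n_proteins,
                            shift = setNames(numeric(20), amino_acids()),
                            baseline_freqs = aa_background_freqs(),
                            length_meanlog = log(400),
                            length_sdlog = 0.45,
                            peptidase_fraction = 0,
                            mutation_rate = 0.1,
                            seed = 1) {
  baseline_freqs <- baseline_freqs[amino_acids()]
  if (anyNA(baseline_freqs) || any(baseline_freqs < 0)) {
    stop("baseline_freqs must be non-negative over the 20 standard residues")
  }
  if (abs(sum(baseline_freqs) - 1) > 1e-12) {
    stop("baseline_freqs must sum to 1 (got ", sum(baseline_freqs), ")")
  }
  shift <- shift[amino_acids()]
  shift[is.na(shift)] <- 0
  if (peptidase_fraction < 0 || peptidase_fraction > 1) {
    stop("peptidase_fraction must lie in [0, 1]")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]")
  }
  shifted <- pmax(baseline_freqs + shift, 0)
  shifted <- shifted / sum(shifted)
  structure(list(
    baseline_freqs = baseline_freqs, shift = shift, shifted_freqs = shifted,
    n_proteins = as.integer(n_proteins), length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, peptidase_fraction = peptidase_fraction,
    mutation_rate = mutation_rate, seed = as.integer(seed)
  ), class = "proteome_regime")
}

#' Generate an annotated peptidase reference library
#'
#' Builds a stand-in for a curated peptidase database: for each requested
#' family a random ancestor sequence is drawn and `n` members are derived
#' from it by independent substitution at rate `divergence`, so that expected
#' pairwise within-family divergence stays below 10%. Headers follow the
#' dialect `SYN000001|FAM=A01|TYPE=A`.
#'
#' @param families A data frame with columns `code` (MEROPS-style family
#'   code, e.g. `"A01"`), `n` (members per family) and `length` (ancestor
#'   length in residues).
#' @param seed Integer RNG seed.
#' @param divergence Per-member substitution rate from the family ancestor
#'   (default 0.04, giving ~8% expected pairwise divergence).
#' @return An object of class `reference_library`: list with `sequences`
#'   (named [Biostrings::AAStringSet]) and `info` (data frame with `id`,
#'   `family`, `catalytic_type`).
#' @seealso [build_kmer_index()], [family_to_catalytic_type()]
#' @export
#' @examples
#' ref <- make_reference_library(
#'   data.frame(code = c("A01", "S08"), n = 3, length = c(350, 400)), seed = 1)
#' ref$info
make_reference_library <- function(families, seed = 1, divergence = 0.04) {
  families <- as.data.frame(families)
  if (nrow(families) == 0) {
    seqs <- Biostrings::AAStringSet(character(0))
    info <- data.frame(id = character(0), family = character(0),
                       catalytic_type = character(0))
    return(structure(list(sequences = seqs, info = info),
                     class = "reference_library"))
  }
  stopifnot(all(c("code", "n", "length") %in% names(families)))
  if (any(families$n < 1)) stop("each family needs n >= 1 members")
  letters1 <- check_family_code(families$code)
  with_seed(seed, {
    ids <- character(0); fams <- character(0); seqs <- character(0)
    counter <- 0L
    for (i in seq_len(nrow(families))) {
      ancestor <- random_protein(families$length[i], aa_background_freqs())
      for (j in seq_len(families$n[i])) {
        counter <- counter + 1L
        ids <- c(ids, sprintf("SYN%06d", counter))
        fams <- c(fams, families$code[i])
        seqs <- c(seqs, mutate_protein(ancestor, divergence))
      }
    }
    types <- vapply(substr(fams, 1, 1), family_to_catalytic_type,
                    character(1), USE.NAMES = FALSE)
    sset <- Biostrings::AAStringSet(seqs)
    names(sset) <- sprintf("%s|FAM=%s|TYPE=%s", ids, fams, substr(fams, 1, 1))
    structure(list(
      sequences = sset,
      info = data.frame(id = ids, family = fams, catalytic_type = types)
    ), class = "reference_library")
  })
}

#' @export
print.reference_library <- function(x, ...) {
  cat("reference_library: ", length(x$sequences), " sequences, ",
      length(unique(x$info$family)), " families\n", sep = "")
  if (nrow(x$info)) print(table(x$info$family))
  invisible(x)
}

#' Parse reference FASTA headers into family annotations
#'
#' The default dialect is the synthetic one (`id|FAM=A01|TYPE=A`). A parser
#' for MEROPS pepunit-style headers (family code inside `[A01.001]`) is
#' bundled, and any custom regex with two capture groups (id, family code)
#' can be supplied.
#'
#' @param headers Character vector of FASTA header lines (without `>`).
#' @param dialect `"synthetic"`, `"merops"`, or a custom regex with capture
#'   groups 1 = id and 2 = family code.
#' @return Data frame with columns `id`, `family`, `catalytic_type`.
#' @export
#' @examples
#' parse_reference_headers("SYN000001|FAM=A01|TYPE=A")
#' parse_reference_headers("MER0000101 pepsin A [A01.001]#A01#", "merops")
parse_reference_headers <- function(headers, dialect = "synthetic") {
  pattern <- switch(dialect,
    synthetic = "^(\\S+?)\\|FAM=([ACGMNSTPU][0-9]+[A-Z]?)\\|TYPE=[A-Z]",
    merops = "^(\\S+).*\\[([ACGMNSTPU][0-9]+)[.#\\]]",
    dialect)
  m <- regmatches(headers, regexec(pattern, headers, perl = TRUE))
  bad <- vapply(m, length, integer(1)) < 3
  if (any(bad)) {
    stop("could not parse reference header(s): ",
         paste(utils::head(headers[bad], 3), collapse = "; "))
  }
  id <- vapply(m, `[`, character(1), 2)
  fam <- vapply(m, `[`, character(1), 3)
  data.frame(id = id, family = fam,
             catalytic_type = vapply(substr(fam, 1, 1),
                                     family_to_catalytic_type, character(1),
                                     USE.NAMES = FALSE))
}

#' Read an annotated reference library from FASTA
#'
#' @param file Path to a FASTA file whose headers carry family codes.
#' @inheritParams parse_reference_headers
#' @return A `reference_library` (see [make_reference_library()]).
#' @export
read_reference_fasta <- function(file, dialect = "synthetic") {
  sset <- Biostrings::readAAStringSet(file)
  info <- parse_reference_headers(names(sset), dialect)
  structure(list(sequences = sset, info = info), class = "reference_library")
}

#' Generate a synthetic proteome with recorded ground truth
#'
#' `floor(n_proteins * peptidase_fraction)` proteins are mutated copies of
#' reference library members (sampled with replacement; their true family is
#' recorded); the remainder are i.i.d. draws from the regime's shifted
#' residue law. Output is bit-reproducible given the regime.
#'
#' @param regime A [proteome_regime()].
#' @param reference A `reference_library`, required when
#'   `peptidase_fraction > 0`.
#' @param species_id Species tag attached to every record.
#' @param group Group label (e.g. `"mesophilic"`).
#' @return List of class `synthetic_proteome` with `sequences` (named
#'   [Biostrings::AAStringSet]) and `truth` (data frame: `id`, `species`,
#'   `group`, `class` = background/peptidase, `family`).
#' @export
#' @examples
#' reg <- proteome_regime(n_proteins = 20, seed = 7)
#' p <- make_proteome(reg, species_id = "sp1", group = "mesophilic")
#' table(p$truth$class)
make_proteome <- function(regime, reference = NULL, species_id = "species1",
                          group = "mesophilic") {
  stopifnot(inherits(regime, "proteome_regime"))
  n_pep <- floor(regime$n_proteins * regime$peptidase_fraction)
  if (n_pep > 0 &&
      (is.null(reference) || length(reference$sequences) == 0)) {
    stop("peptidase_fraction > 0 requires a non-empty reference library")
  }
  with_seed(regime$seed, {
    n_bg <- regime$n_proteins - n_pep
    fams <- rep(NA_character_, regime$n_proteins)
    cls <- rep("background", regime$n_proteins)
    seqs <- character(regime$n_proteins)
    if (n_pep > 0) {
      pick <- sample(length(reference$sequences), n_pep, replace = TRUE)
      src <- as.character(reference$sequences)[pick]
      seqs[seq_len(n_pep)] <- vapply(src, mutate_protein, character(1),
                                     rate = regime$mutation_rate,
                                     USE.NAMES = FALSE)
      fams[seq_len(n_pep)] <- reference$info$family[pick]
      cls[seq_len(n_pep)] <- "peptidase"
    }
    if (n_bg > 0) {
      lens <- pmax(30L, round(rlnorm(n_bg, regime$length_meanlog,
                                     regime$length_sdlog)))
      seqs[n_pep + seq_len(n_bg)] <- random_protein(lens,
                                                    regime$shifted_freqs)
    }
    ids <- sprintf("%s_P%05d", species_id, seq_len(regime$n_proteins))
    sset <- Biostrings::AAStringSet(seqs)
    names(sset) <- ids
    structure(list(
      sequences = sset,
      truth = data.frame(id = ids, species = species_id, group = group,
                         class = cls, family = fams)
    ), class = "synthetic_proteome")
  })
}

#' Generate a hallmark-labelled aspartic-peptidase test set
#'
#' Positives contain the five A1A hallmarks (`D[TS]G`, `Y`, `XXG`, `D[TS]G`,
#' `XXG`; X hydrophobic) in order, embedded at random positions in a
#' glycine-free random background so no accidental extra motifs arise.
#' Negatives provably fail the scan: they are built either without any
#' glycine (first motif impossible) or with the first three motifs followed
#' by a glycine-free tail (fourth motif impossible).
#'
#' @param n_pos,n_neg Numbers of positive / negative sequences (>= 0).
#' @param length Approximate sequence length.
#' @param seed Integer RNG seed.
#' @return List of class `hallmark_set` with `sequences` (named
#'   [Biostrings::AAStringSet]) and `truth` (data frame: `id`, `functional`).
#' @seealso [scan_hallmarks()], [filter_functional()]
#' @export
#' @examples
#' hs <- make_hallmark_set(3, 3, seed = 1)
#' hs$truth
make_hallmark_set <- function(n_pos, n_neg, length = 400, seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, length >= 60)
  hydro <- c("A", "F", "I", "L", "M", "V")
  no_g <- setdiff(amino_acids(), "G")
  rand_nog <- function(n) paste0(sample(no_g, n, replace = TRUE),
                                 collapse = "")
  motif <- function(i) {
    switch(i,
      paste0("D", sample(c("T", "S"), 1), "G"),
      "Y",
      paste0(paste0(sample(hydro, 2, replace = TRUE), collapse = ""), "G"),
      paste0("D", sample(c("T", "S"), 1), "G"),
      paste0(paste0(sample(hydro, 2, replace = TRUE), collapse = ""), "G"))
  }
  with_seed(seed, {
    gap <- function() rand_nog(sample(5:max(5, length %/% 8), 1))
    pos <- vapply(seq_len(n_pos), function(i) {
      paste0(gap(), motif(1), gap(), motif(2), gap(), motif(3), gap(),
             motif(4), gap(), motif(5), gap())
    }, character(1))
    neg <- vapply(seq_len(n_neg), function(i) {
      if (runif(1) < 0.5) {
        rand_nog(length)                      # no glycine at all
      } else {                                # lacks the second D[TS]G
        paste0(gap(), motif(1), gap(), motif(2), gap(), motif(3),
               rand_nog(length %/% 2))
      }
    }, character(1))
    ids <- c(sprintf("POS%04d", seq_len(n_pos)),
             sprintf("NEG%04d", seq_len(n_neg)))
    sset <- Biostrings::AAStringSet(c(pos, neg))
    names(sset) <- ids
    structure(list(
      sequences = sset,
      truth = data.frame(id = ids,
                         functional = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
    ), class = "hallmark_set")
  })
}
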
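# Best-hit peptidase family assignment: k-mer prescreen + Smith-Waterman
# rescoring against an annotated reference library.

#' Map a family code's catalytic letter to its catalytic type name
#'
#' The leading letter of a MEROPS-style family code encodes the catalytic
#' mechanism: A aspartic, C cysteine, G glutamic, M metallo, N asparagine,
#' S serine, T threonine, P mixed, U unknown.
#'
#' @param family_code Family code(s) (e.g. `"A01"`) or bare catalytic
#'   letter(s).
#' @return Character vector of catalytic type names.
#' @export
#' @examples
#' family_to_catalytic_type(c("A01", "S08", "P01"))
family_to_catalytic_type <- function(family_code) {
  map <- c(A = "Aspartic", C = "Cysteine", G = "Glutamic", M = "Metallo",
           N = "Asparagine", S = "Serine", T = "Threonine", P = "Mixed",
           U = "Unknown")
  if (any(!nzchar(family_code))) stop("empty family code")
  out <- map[substr(family_code, 1, 1)]
  if (anyNA(out)) {
    stop("unknown catalytic letter in family code(s): ",
         paste(family_code[is.na(out)], collapse = ", "))
  }
  unname(out)
}

#' Canonical catalytic type order used in count profiles
#' @return Character vector of the nine catalytic type names.
#' @export
catalytic_types <- function() {
  c("Serine", "Aspartic", "Metallo", "Threonine", "Cysteine", "Glutamic",
    "Asparagine", "Mixed", "Unknown")
}

#' Default mining parameters
#'
#' Thresholds of the best-hit classifier. The k-mer prescreen ranks reference
#' entries by the number of distinct shared k-mers and passes the top
#' `max_candidates` with at least `min_shared_kmers` shared k-mers to
#' Smith-Waterman rescoring (BLOSUM62, affine gap cost `11 + L` for a gap of
#' length L). A hit is emitted only if raw score, percent identity and query
#' coverage all pass their thresholds.
#'
#' @param k k-mer size (3-6).
#' @param min_shared_kmers Minimum distinct shared k-mers to become a
#'   candidate.
#' @param min_score Minimum Smith-Waterman raw score.
#' @param min_identity Minimum percent identity over aligned columns.
#' @param min_coverage Minimum aligned fraction of the query.
#' @param max_candidates Candidates rescored per query.
#' @return A named list of class `mining_params`.
#' @export
mining_params <- function(k = 4, min_shared_kmers = 8, min_score = 60,
                          min_identity = 30, min_coverage = 0.5,
                          max_candidates = 50) {
  if (k < 3 || k > 6) stop("k must lie in 3..6")
  structure(list(k = as.integer(k), min_shared_kmers = min_shared_kmers,
                 min_score = min_score, min_identity = min_identity,
                 min_coverage = min_coverage,
                 max_candidates = max_candidates),
            class = "mining_params")
}

# Distinct k-mers of one sequence.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1), k:n))
}

#' Build a k-mer index over a reference library
#'
#' Maps every distinct k-mer of every reference entry to the entries
#' containing it; the prescreen stage of [classify_protein()].
#'
#' @param reference A `reference_library` (see [make_reference_library()]).
#' @param k k-mer size (3-6).
#' @return An object of class `kmer_index`.
#' @export
#' @examples
#' ref <- make_reference_library(data.frame(code = "A01", n = 2, length = 80),
#'                               seed = 1)
#' idx <- build_kmer_index(ref, k = 4)
#' idx
build_kmer_index <- function(reference, k = 4) {
  stopifnot(inherits(reference, "reference_library"))
  if (k < 3 || k > 6) stop("k must lie in 3..6")
  if (length(reference$sequences) == 0) {
    stop("cannot index an empty reference library")
  }
  seqs <- as.character(reference$sequences)
  post <- new.env(hash = TRUE, parent = emptyenv())
  n_postings <- 0L
  for (i in seq_along(seqs)) {
    for (km in seq_kmers(seqs[i], k)) {
      post[[km]] <- c(post[[km]], i)
      n_postings <- n_postings + 1L
    }
  }
  structure(list(k = as.integer(k), postings = post,
                 n_postings = n_postings, reference = reference),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k=", x$k, ", ", length(x$reference$sequences),
      " reference entries, ", length(ls(x$postings)), " distinct k-mers, ",
      x$n_postings, " postings\n", sep = "")
  invisible(x)
}

# Count shared distinct k-mers between a query and each reference entry.
shared_kmer_counts <- function(query, index) {
  kq <- seq_kmers(query, index$k)
  hits <- unlist(lapply(kq, function(km) index$postings[[km]]),
                 use.names = FALSE)
  if (length(hits) == 0) return(integer(0))
  tab <- tabulate(hits, nbins = length(index$reference$sequences))
  which_hit <- which(tab > 0)
  setNames(tab[which_hit], which_hit)
}

# Extended BLOSUM62: standard 20 letters from the canonical matrix, plus
# zero-scoring rows/columns for the non-standard letters B, J, O, U, X, Z so
# they are mismatch-neutral in alignments.
blosum62_extended <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      b62 <- e$BLOSUM62
      letters <- c(amino_acids(), .aa_nonstandard)
      m <- matrix(0L, length(letters), length(letters),
                  dimnames = list(letters, letters))
      m[amino_acids(), amino_acids()] <- b62[amino_acids(), amino_acids()]
      cache <<- m
    }
    cache
  }
})

# Smith-Waterman rescoring of a query against candidate references.
# Returns a data frame of score / identity / coverage per candidate.
sw_rescore <- function(query, subjects) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = subjects, subject = query, type = "local",
    substitutionMatrix = blosum62_extended(),
    gapOpening = 11, gapExtension = 1, scoreOnly = FALSE)
  qlen <- nchar(query)
  qstart <- Biostrings::start(Biostrings::subject(aln))
  qend <- Biostrings::end(Biostrings::subject(aln))
  data.frame(
    score = Biostrings::score(aln),
    identity = Biostrings::pid(aln, type = "PID1"),
    coverage = (qend - qstart + 1) / qlen
  )
}

#' Classify one protein against the reference library
#'
#' Candidates are ranked by distinct shared k-mers; the top
#' `max_candidates` are rescored by local Smith-Waterman alignment (BLOSUM62,
#' gap open 11 / extend 1); the best hit is emitted iff it passes all
#' thresholds. Score ties break by higher identity, then lexicographic
#' reference id, so classification is deterministic.
#'
#' @param query One amino-acid sequence (character or
#'   [Biostrings::AAString]).
#' @param index A [build_kmer_index()] result.
#' @param params A [mining_params()] list.
#' @param query_id Identifier recorded in the result.
#' @return One-row data frame: `query_id`, `status` (`"hit"`, `"no_call"`),
#'   `reason`, `family`, `catalytic_type`, `score`, `identity`, `coverage`.
#' @export
#' @examples
#' ref <- make_reference_library(data.frame(code = "A01", n = 2, length = 90),
#'                               seed = 1)
#' idx <- build_kmer_index(ref)
#' classify_protein(as.character(ref$sequences[[1]]), idx)
classify_protein <- function(query, index, params = mining_params(),
                             query_id = "query") {
  stopifnot(inherits(index, "kmer_index"))
  query <- unname(as_aa_character(query)[1])
  no_call <- function(reason) {
    data.frame(query_id = query_id, status = "no_call", reason = reason,
               family = NA_character_, catalytic_type = NA_character_,
               score = NA_real_, identity = NA_real_, coverage = NA_real_)
  }
  n_std <- sum(aa_chars(query) %in% amino_acids())
  if (n_std < index$k) return(no_call("too short"))
  shared <- shared_kmer_counts(query, index)
  shared <- shared[shared >= params$min_shared_kmers]
  if (length(shared) == 0) return(no_call("no candidate"))
  ids <- index$reference$info$id[as.integer(names(shared))]
  ord <- order(-shared, ids)
  cand <- as.integer(names(shared))[ord]
  cand <- cand[seq_len(min(length(cand), params$max_candidates))]
  res <- sw_rescore(query, index$reference$sequences[cand])
  res$id <- index$reference$info$id[cand]
  res$family <- index$reference$info$family[cand]
  best <- res[order(-res$score, -res$identity, res$id), ][1, ]
  if (best$score < params$min_score) return(no_call("below min_score"))
  if (best$identity < params$min_identity) {
    return(no_call("below min_identity"))
  }
  if (best$coverage < params$min_coverage) {
    return(no_call("below min_coverage"))
  }
  data.frame(query_id = query_id, status = "hit", reason = NA_character_,
             family = best$family,
             catalytic_type = family_to_catalytic_type(best$family),
             score = best$score, identity = best$identity,
             coverage = best$coverage)
}

#' Mine a whole proteome for peptidases
#'
#' Applies [classify_protein()] to every sequence and returns the annotation
#' table (hits and no-calls) tagged with species and group.
#'
#' @param sequences Named character vector or [Biostrings::AAStringSet].
#' @param index A [build_kmer_index()] result.
#' @param params A [mining_params()] list.
#' @param species,group Tags recorded on every row.
#' @return Data frame of per-query annotations.
#' @export
mine_proteome <- function(sequences, index, params = mining_params(),
                          species = "species1", group = NA_character_) {
  seqs <- as_aa_character(sequences)
  rows <- lapply(seq_along(seqs), function(i) {
    classify_protein(seqs[i], index, params, query_id = names(seqs)[i])
  })
  out <- do.call(rbind, rows)
  out$species <- species
  out$group <- group
  out
}

#' Aggregate annotations into a species-by-category count matrix
#'
#' @param annotations Data frame as returned by [mine_proteome()] (possibly
#'   several species row-bound together); no-call rows are ignored.
#' @param level `"catalytic_type"` (nine canonical columns) or `"family"`
#'   (sorted family codes observed).
#' @param species_levels Optional character vector fixing the row set, so
#'   species with zero hits appear as all-zero rows; defaults to the species
#'   present in `annotations`.
#' @return A [count_matrix()]; row sums equal the number of annotated
#'   (hit) queries per species at either level.
#' @export
profile_species <- function(annotations,
                            level = c("catalytic_type", "family"),
                            species_levels = NULL) {
  level <- match.arg(level)
  stopifnot(all(c("species", "group", "status", level) %in%
                  names(annotations)))
  if (is.null(species_levels)) species_levels <- unique(annotations$species)
  hits <- annotations[annotations$status == "hit", , drop = FALSE]
  cats <- if (level == "catalytic_type") catalytic_types()
          else sort(unique(hits$family))
  if (length(cats) == 0) cats <- "none"
  tab <- table(factor(hits$species, levels = species_levels),
               factor(hits[[level]], levels = cats))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  grp <- vapply(species_levels, function(s) {
    g <- unique(annotations$group[annotations$species == s])
    if (length(g) == 0) "unknown" else g[1]
  }, character(1))
  count_matrix(m, grp)
}
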
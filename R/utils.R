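# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Coerce character / AAString / AAStringSet input to a named character vector
# of upper-case sequences.
as_aa_character <- function(x, default_prefix = "seq") {
  if (inherits(x, "AAStringSet")) {
    out <- as.character(x)
  } else if (inherits(x, "AAString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected a character vector, AAString or AAStringSet, got ",
         class(x)[1])
  }
  out <- toupper(out)
  if (is.null(names(out)) && length(out) > 0) {
    names(out) <- sprintf("%s%d", default_prefix, seq_along(out))
  }
  out
}

# Split one sequence into its residue characters.
aa_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Random protein sequence(s) from a residue frequency law.
random_protein <- function(lengths, freqs) {
  freqs <- freqs[amino_acids()]
  vapply(lengths, function(n) {
    paste0(sample(amino_acids(), n, replace = TRUE, prob = freqs),
           collapse = "")
  }, character(1))
}

# Mutate a sequence by uniform substitution over the 19 alternative residues;
# no indels. Returns the mutated sequence.
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- aa_chars(seq)
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a) {
      sample(setdiff(amino_acids(), a), 1)
    }, character(1))
  }
  paste0(ch, collapse = "")
}

# Validate a MEROPS-style family code, returning its leading catalytic letter.
check_family_code <- function(code) {
  ok <- grepl("^[ACGMNSTPU][0-9]+[A-Z]?$", code)
  if (any(!ok)) {
    stop("malformed family code(s): ", paste(code[!ok], collapse = ", "),
         " (expected e.g. 'A01', 'S08', 'C14A')")
  }
  substr(code, 1, 1)
}
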
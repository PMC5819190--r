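# Amino-acid composition profiles and mesophile-vs-thermophile shift tests.

#' Per-sequence amino-acid composition
#'
#' Percentage of each of the twenty standard residues per sequence, computed
#' over standard residues only: ambiguity and non-standard letters (B, J, O,
#' U, X, Z) are excluded from both numerator and denominator. Class
#' percentages (charged, polar, hydrophobic; EMBOSS PEPSTATS definitions,
#' overlapping by design) are included.
#'
#' @param sequences Character vector or [Biostrings::AAStringSet].
#' @return Data frame: `id`, one percent column per residue, `charged`,
#'   `polar`, `hydrophobic`, and `n_residues` (standard residues counted).
#'   The twenty residue percentages sum to 100 per row.
#' @export
#' @examples
#' aa_composition(c(p1 = "ACDE", p2 = "AAAA"))
aa_composition <- function(sequences) {
  seqs <- as_aa_character(sequences)
  if (length(seqs) == 0) {
    stop("no sequences given")
  }
  sset <- Biostrings::AAStringSet(seqs)
  freq <- Biostrings::alphabetFrequency(sset)
  counts <- freq[, amino_acids(), drop = FALSE]
  n_std <- rowSums(counts)
  if (any(n_std == 0)) {
    stop("sequence(s) without any standard residue: ",
         paste(names(seqs)[n_std == 0], collapse = ", "))
  }
  pct <- sweep(counts, 1, n_std, "/") * 100
  out <- data.frame(id = names(seqs), pct, check.names = FALSE,
                    row.names = NULL)
  out$charged <- rowSums(pct[, .aa_charged, drop = FALSE])
  out$polar <- rowSums(pct[, .aa_polar, drop = FALSE])
  out$hydrophobic <- rowSums(pct[, .aa_hydrophobic, drop = FALSE])
  out$n_residues <- as.integer(n_std)
  out
}

#' Physicochemical class percentages of a sequence
#'
#' Charged = D,E,H,K,R; polar = D,E,H,K,N,Q,R,S,T; hydrophobic (non-polar) =
#' A,C,F,G,I,L,M,P,V,W,Y. Charged is a subset of polar, so the three values
#' need not sum to 100.
#'
#' @param sequence One amino-acid sequence.
#' @return Named numeric vector `c(charged, polar, hydrophobic)` in percent.
#' @export
#' @examples
#' class_fractions("DS")
class_fractions <- function(sequence) {
  p <- aa_composition(sequence)
  c(charged = p$charged, polar = p$polar, hydrophobic = p$hydrophobic)
}

#' Aggregate per-protein compositions to species level
#'
#' Species profiles are unweighted means of per-protein percentages by
#' default (every protein counts equally); `weighted = TRUE` instead pools
#' residue counts across proteins, i.e. length-weights the average.
#'
#' @param sequences Character vector or [Biostrings::AAStringSet].
#' @param species Species tag per sequence.
#' @param weighted Length-weight the species mean (default `FALSE`).
#' @return Data frame with one row per species, same columns as
#'   [aa_composition()].
#' @export
species_composition <- function(sequences, species, weighted = FALSE) {
  prof <- aa_composition(sequences)
  stopifnot(length(species) == nrow(prof))
  vars <- c(amino_acids(), "charged", "polar", "hydrophobic")
  agg <- lapply(split(seq_len(nrow(prof)), species), function(i) {
    w <- if (weighted) prof$n_residues[i] else rep(1, length(i))
    v <- vapply(vars, function(vn) {
      sum(prof[[vn]][i] * w) / sum(w)
    }, numeric(1))
    c(v, n_residues = sum(prof$n_residues[i]))
  })
  out <- data.frame(id = names(agg), do.call(rbind, agg),
                    check.names = FALSE, row.names = NULL)
  out$n_residues <- as.integer(out$n_residues)
  out
}

#' Test compositional shifts between two groups
#'
#' Runs one two-group location test per composition variable (twenty
#' residues plus the three classes) and reports the direction of change of
#' the second group relative to the first at the requested alpha. The
#' default is Welch's unequal-variance t-test on per-unit profiles (typically
#' species means); Student's pooled test and a paired test on matched unit
#' lists are available. Raw P values are primary; Benjamini-Hochberg
#' adjusted values can be reported alongside.
#'
#' @param profiles Data frame of composition profiles (as from
#'   [aa_composition()] or [species_composition()]).
#' @param groups Factor or character vector, one label per row, with exactly
#'   two levels; the reported difference is `mean(level 2) - mean(level 1)`.
#' @param mode `"welch"`, `"student"` or `"paired"`. Paired mode requires
#'   the two groups to be matched in listed order and of equal size.
#' @param alpha Significance level for the direction call (default 0.05).
#' @param adjust Also report BH-adjusted P values (default `TRUE`).
#' @return Data frame: `variable`, `mean_1`, `mean_2`, `diff`, `t`, `df`,
#'   `p_value`, `p_adjusted`, `direction` (`"+"`, `"-"`, `"ns"`).
#' @export
#' @examples
#' prof <- aa_composition(c(a = "AAEE", b = "AAED", c = "LLKK", d = "LLKR"))
#' compare_groups(prof, c("g1", "g1", "g2", "g2"))
compare_groups <- function(profiles, groups,
                           mode = c("welch", "student", "paired"),
                           alpha = 0.05, adjust = TRUE) {
  mode <- match.arg(mode)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two group levels")
  stopifnot(length(groups) == nrow(profiles))
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  if (mode == "paired") {
    if (length(g1) != length(g2)) {
      stop("paired mode requires equal-sized, matched unit lists ",
           "(got ", length(g1), " vs ", length(g2), ")")
    }
    if (length(g1) < 2) stop("paired mode needs >= 2 pairs")
  } else if (length(g1) < 2 || length(g2) < 2) {
    stop("need >= 2 units per group")
  }
  vars <- intersect(c(amino_acids(), "charged", "polar", "hydrophobic"),
                    names(profiles))
  rows <- lapply(vars, function(v) {
    r <- t_test(profiles[[v]][g1], profiles[[v]][g2], mode = mode)
    data.frame(variable = v, mean_1 = r$mean_x, mean_2 = r$mean_y,
               diff = r$diff, t = r$t, df = r$df, p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust) p.adjust(out$p_value, "BH") else NA_real_
  out$direction <- ifelse(out$p_value < alpha,
                          ifelse(out$diff > 0, "+", "-"), "ns")
  attr(out, "groups") <- levels(groups)
  attr(out, "mode") <- mode
  out
}
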
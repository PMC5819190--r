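# Bundled survey fixtures: peptidase gene counts for 23 fungal species and
# structural metrics of twelve A1A aspartic peptidases.

#' Peptidase gene counts of 23 fungal species by catalytic type
#'
#' A species-by-catalytic-type count matrix from a comparative survey of
#' fungal genomes: 8 mesophilic, 2 thermotolerant and 13 thermophilic
#' species, with the number of putative peptidase genes per catalytic type
#' (Serine, Aspartic, Metallo, Threonine, Cysteine, Glutamic, Asparagine,
#' Mixed, Unknown). Thermotolerant species are conventionally excluded from
#' two-group comparisons.
#'
#' @return A [count_matrix()] (23 species x 9 catalytic types).
#' @seealso [anosim()], [simper()], [subset_groups()]
#' @export
#' @examples
#' m <- fungal_peptidase_counts()
#' table(m$group)
fungal_peptidase_counts <- function() {
  read_count_matrix(system.file("extdata", "fungal_peptidase_counts.tsv",
                                package = "thermopep", mustWork = TRUE))
}

#' Structural metrics of twelve A1A aspartic peptidases
#'
#' Per-protein metrics of homology models of one well-characterized
#' pepsin-like aspartic peptidase per species: molecular mass (kDa), pI,
#' secondary-structure element counts, surface area and volume (tool-specific
#' units), and the number of interior cavities. The non-thermophilic group
#' (labelled `mesophilic` here) includes one thermotolerant species; cavity
#' counts are the variable of interest for the thermostability comparison.
#'
#' @return Data frame with columns `species`, `group`, `mw_kda`, `pi`,
#'   `helix`, `strands`, `sheets`, `area`, `volume`, `n_cavities`.
#' @seealso [compare_structural_groups()]
#' @export
#' @examples
#' tab <- aspartic_peptidase_structures()
#' split(tab$n_cavities, tab$group)
aspartic_peptidase_structures <- function() {
  read.delim(system.file("extdata", "aspartic_peptidase_structures.tsv",
                         package = "thermopep", mustWork = TRUE),
             check.names = FALSE, stringsAsFactors = FALSE)
}
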
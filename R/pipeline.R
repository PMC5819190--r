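# End-to-end study orchestration: simulate or ingest, mine, profile, test,
# and write a reproducible report bundle.

#' Configure a comparative peptidase study
#'
#' Two input modes are supported. `"fixture"` runs the statistics stages on
#' the bundled survey tables ([fungal_peptidase_counts()],
#' [aspartic_peptidase_structures()]). `"synthetic"` generates a full study
#' from the ground-truth simulators — reference library, one proteome per
#' species (thermophilic species get the compositional shift and a reduced
#' peptidase complement), hallmark set — then mines and tests them.
#'
#' @param mode `"fixture"` or `"synthetic"`.
#' @param seed Master RNG seed; all stage seeds derive from it.
#' @param n_species Named vector: species per group (synthetic mode).
#' @param n_proteins Proteins per synthetic proteome.
#' @param peptidase_fraction Fraction of each group's proteome drawn from
#'   the reference library; the thermophilic value may differ to emulate a
#'   reduced peptidase complement, e.g. `c(mesophilic = 0.08,
#'   thermophilic = 0.05)`.
#' @param mutation_rate Substitution rate of reference-derived peptidases.
#' @param reference_families Data frame for [make_reference_library()].
#' @param n_hallmark Named vector `c(pos = , neg = )` for
#'   [make_hallmark_set()].
#' @param metric,relativize Distance configuration for [anosim()] /
#'   [simper()].
#' @param n_perm Permutations for ANOSIM and Kruskal-Wallis.
#' @param alpha Significance level for direction calls.
#' @param groups The two group labels compared (others, e.g. thermotolerant,
#'   are excluded from two-group statistics).
#' @return A validated list of class `study_config`.
#' @seealso [run_study()]
#' @export
study_config <- function(mode = c("fixture", "synthetic"), seed = 1,
                         n_species = c(mesophilic = 5, thermophilic = 5),
                         n_proteins = 60,
                         peptidase_fraction = c(mesophilic = 0.10,
                                                thermophilic = 0.06),
                         mutation_rate = 0.05,
                         reference_families = data.frame(
                           code = c("A01", "S08", "M28", "C19"),
                           n = 3, length = c(350, 400, 380, 360)),
                         n_hallmark = c(pos = 10, neg = 10),
                         metric = "braycurtis", relativize = FALSE,
                         n_perm = 9999, alpha = 0.05,
                         groups = c("mesophilic", "thermophilic")) {
  mode <- match.arg(mode)
  stopifnot(length(groups) == 2, n_perm >= 1)
  if (mode == "synthetic") {
    if (is.null(names(n_species))) names(n_species) <- groups
    if (length(peptidase_fraction) == 1) {
      peptidase_fraction <- setNames(rep(peptidase_fraction, 2), groups)
    }
    if (any(n_species < 2)) stop("need >= 2 species per group")
    check_family_code(reference_families$code)
  }
  structure(list(mode = mode, seed = as.integer(seed),
                 n_species = n_species, n_proteins = n_proteins,
                 peptidase_fraction = peptidase_fraction,
                 mutation_rate = mutation_rate,
                 reference_families = reference_families,
                 n_hallmark = n_hallmark, metric = metric,
                 relativize = relativize, n_perm = n_perm, alpha = alpha,
                 groups = groups),
            class = "study_config")
}

#' Run a comparative peptidase study end to end
#'
#' Executes the configured stages and (optionally) writes a report bundle:
#' count matrix, ANOSIM / SIMPER / Kruskal-Wallis reports, composition shift
#' table, hallmark partition report, and a JSON manifest of parameters and
#' input checksums. Outputs are pure functions of (config, seed): a rerun
#' with the same configuration reproduces the bundle byte for byte.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List of stage results (class `study_result`), invisibly when
#'   `out_dir` is given.
#' @export
#' @examples
#' res <- run_study(study_config("fixture", n_perm = 199))
#' res$anosim
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  res <- list(config = config)
  if (config$mode == "fixture") {
    counts <- fungal_peptidase_counts()
    res$counts <- counts
    two <- subset_groups(counts, config$groups)
    res$anosim <- anosim(two, n_perm = config$n_perm, seed = config$seed,
                         metric = config$metric,
                         relativize = config$relativize)
    res$simper <- simper(two, pair = config$groups,
                         relativize = config$relativize)
    st <- aspartic_peptidase_structures()
    res$structures <- st
    res$cavity_kw <- compare_structural_groups(
      st$n_cavities, st$group, n_perm = max(config$n_perm, 1e4),
      seed = config$seed)
  } else {
    res <- c(res, run_synthetic_study(config))
  }
  if (!is.null(out_dir)) {
    write_study_bundle(res, out_dir)
    return(invisible(res))
  }
  structure(res, class = "study_result")
}

run_synthetic_study <- function(config) {
  groups <- config$groups
  ref <- make_reference_library(config$reference_families,
                                seed = config$seed)
  idx <- build_kmer_index(ref)
  shift0 <- setNames(numeric(20), amino_acids())
  species <- list()
  for (g in groups) {
    for (i in seq_len(config$n_species[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      reg <- proteome_regime(
        n_proteins = config$n_proteins,
        shift = if (g == groups[2]) thermophilic_shift() else shift0,
        peptidase_fraction = config$peptidase_fraction[[g]],
        mutation_rate = config$mutation_rate,
        seed = config$seed + 1000L * match(g, groups) + i)
      species[[sid]] <- make_proteome(reg, ref, species_id = sid, group = g)
    }
  }
  annotations <- do.call(rbind, lapply(names(species), function(sid) {
    mine_proteome(species[[sid]]$sequences, idx,
                  species = sid, group = species[[sid]]$truth$group[1])
  }))
  counts <- profile_species(annotations, species_levels = names(species))
  comp <- species_composition(
    unlist(lapply(species, function(s) as.character(s$sequences))),
    rep(names(species), vapply(species, function(s) length(s$sequences),
                               integer(1))))
  grp_of <- vapply(species, function(s) s$truth$group[1], character(1))
  hs <- make_hallmark_set(config$n_hallmark[["pos"]],
                          config$n_hallmark[["neg"]],
                          seed = config$seed + 77L)
  part <- filter_functional(hs$sequences)
  list(
    reference = ref,
    truth = do.call(rbind, lapply(species, `[[`, "truth")),
    annotations = annotations,
    counts = counts,
    anosim = anosim(counts, n_perm = config$n_perm, seed = config$seed,
                    metric = config$metric,
                    relativize = config$relativize),
    simper = simper(counts, pair = groups,
                    relativize = config$relativize),
    composition = compare_groups(comp, grp_of[comp$id],
                                 alpha = config$alpha),
    hallmark_truth = hs$truth,
    hallmark = part
  )
}

write_study_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- res$config
  p <- function(f) file.path(out_dir, f)
  if (!is.null(res$counts)) write_count_matrix(res$counts, p("counts.tsv"))
  jsonlite::write_json(
    list(R = res$anosim$R, p_value = res$anosim$p_value,
         n_perm = res$anosim$n_perm, metric = res$anosim$metric),
    p("anosim.json"), auto_unbox = TRUE, digits = NA)
  sim <- as.data.frame(res$simper)
  write.table(sim, p("simper.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(overall_pct = attr(res$simper, "overall_pct"),
         pair = attr(res$simper, "pair")),
    p("simper_overall.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$cavity_kw)) {
    jsonlite::write_json(
      res$cavity_kw[c("H", "df", "p_chi2", "p_perm", "n_perm")],
      p("cavity_kw.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$composition)) {
    write.table(res$composition, p("composition_shifts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$hallmark)) {
    write.table(res$hallmark$report, p("hallmark_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  fixture_files <- if (config$mode == "fixture") {
    system.file("extdata",
                c("fungal_peptidase_counts.tsv",
                  "aspartic_peptidase_structures.tsv"),
                package = "thermopep")
  } else character(0)
  manifest <- list(
    package = "thermopep",
    version = as.character(utils::packageVersion("thermopep")),
    seed = config$seed,
    mode = config$mode,
    parameters = unclass(config)[setdiff(names(config),
                                         "reference_families")],
    input_checksums = as.list(tools::md5sum(fixture_files))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result (mode:", x$config$mode, ")\n")
  if (!is.null(x$anosim)) print(x$anosim)
  if (!is.null(x$simper)) {
    cat(sprintf("SIMPER overall between-group dissimilarity: %.2f%%\n",
                attr(x$simper, "overall_pct")))
  }
  if (!is.null(x$cavity_kw)) print(x$cavity_kw)
  invisible(x)
}
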
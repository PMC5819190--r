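# Structure-level metrics: PDB ingestion, interior cavity counting on a
# probe-augmented voxel grid, and sequence-derived molecular weight / pI.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (waters skipped by default), counts HELIX and
#' SHEET records, and assigns van der Waals radii by element (C 1.70, N 1.55,
#' O 1.52, S 1.80, H 1.20 Angstrom, 1.70 otherwise). The element is taken
#' from PDB columns 77-78 when present, with a fallback to the first letter
#' of the atom name. Tokenizing is delegated to [bio3d::read.pdb()].
#'
#' @param file Path to a PDB file with at least one ATOM record.
#' @param keep_water Keep water (HOH/WAT/DOD) records (default `FALSE`).
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `element`, `resid`, `chain`, `x`, `y`, `z`, `radius`),
#'   `helix_records`, `sheet_records`, `source`.
#' @seealso [count_cavities()], [make_structure()]
#' @export
read_pdb <- function(file, keep_water = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e) {
                    stop("could not parse PDB file ", file, ": ",
                         conditionMessage(e))
                  })
  a <- pdb$atom
  if (nrow(a) == 0) stop("no ATOM records in ", file)
  if (!keep_water) {
    a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
    if (nrow(a) == 0) stop("no non-water ATOM records in ", file)
  }
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad) > 0) {
    stop("malformed coordinate field at ATOM record ", bad[1],
         " (serial ", a$eleno[bad[1]], ") in ", file)
  }
  elem <- toupper(trimws(a$elesy))
  fallback <- !nzchar(elem) | is.na(elem)
  if (any(fallback)) {
    elem[fallback] <- substr(gsub("[^A-Za-z].*", "",
                                  trimws(a$elety[fallback])), 1, 1)
  }
  radius <- unname(.vdw_radius[elem])
  radius[is.na(radius)] <- .vdw_default
  atoms <- data.frame(element = elem, resid = a$resid, chain = a$chain,
                      x = a$x, y = a$y, z = a$z, radius = radius)
  structure(list(
    atoms = atoms,
    helix_records = if (is.null(pdb$helix)) 0L else
      length(pdb$helix$start),
    sheet_records = if (is.null(pdb$sheet)) 0L else
      length(pdb$sheet$start),
    source = file
  ), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ", nrow(x$atoms), " atoms, ", x$helix_records,
      " HELIX and ", x$sheet_records, " SHEET records (", x$source, ")\n",
      sep = "")
  invisible(x)
}

#' Count interior cavities of a structure by voxel flood fill
#'
#' The bounding box, padded by the largest atom radius plus the probe, is
#' voxelized at `grid_res`. Voxels within `radius + probe_radius` of any
#' atom center are occupied (the probe-augmented solid). A 6-connected flood
#' fill from all boundary voxels marks the exterior; remaining empty
#' connected components with at least `min_voxels` voxels are interior
#' cavities. Volumes are voxel counts times `grid_res^3`.
#'
#' Absolute cavity counts depend on the chosen resolution, probe radius and
#' size threshold, so group comparisons should hold these fixed.
#'
#' @param model A `structure_model`.
#' @param grid_res Voxel edge length in Angstrom (default 0.8).
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4,
#'   water).
#' @param min_voxels Minimum voxels for a component to count as a cavity
#'   (default 5).
#' @param max_grid_voxels Guard on total grid size; exceeded grids raise an
#'   error suggesting a coarser resolution (default 3e7).
#' @return List of class `cavity_report`: `n_cavities`, `voxel_counts`,
#'   `volumes` (Angstrom^3, descending), `grid_res`, `probe_radius`,
#'   `min_voxels`.
#' @export
#' @examples
#' s <- make_structure(1, shell_radius_A = 8, seed = 1)
#' count_cavities(s)$n_cavities
count_cavities <- function(model, grid_res = 0.8, probe_radius = 1.4,
                           min_voxels = 5, max_grid_voxels = 3e7) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0) stop("structure has no atoms")
  reach <- a$radius + probe_radius
  pad <- max(reach) + grid_res
  lo <- c(min(a$x), min(a$y), min(a$z)) - pad
  hi <- c(max(a$x), max(a$y), max(a$z)) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / grid_res)) + 1L)
  if (prod(dims) > max_grid_voxels) {
    stop("voxel grid of ", prod(dims), " voxels exceeds the budget (",
         format(max_grid_voxels, scientific = FALSE),
         "); use a coarser grid_res")
  }
  occ <- array(FALSE, dim = dims)
  # mark voxels within reach of each atom over its local subgrid
  ijk0 <- cbind(floor((a$x - lo[1]) / grid_res),
                floor((a$y - lo[2]) / grid_res),
                floor((a$z - lo[3]) / grid_res))
  rv <- ceiling(reach / grid_res) + 1L
  ax <- (a$x - lo[1]) / grid_res
  ay <- (a$y - lo[2]) / grid_res
  az <- (a$z - lo[3]) / grid_res
  r2 <- (reach / grid_res)^2
  for (t in seq_len(nrow(a))) {
    i <- max(0L, ijk0[t, 1] - rv[t]):min(dims[1] - 1L, ijk0[t, 1] + rv[t])
    j <- max(0L, ijk0[t, 2] - rv[t]):min(dims[2] - 1L, ijk0[t, 2] + rv[t])
    k <- max(0L, ijk0[t, 3] - rv[t]):min(dims[3] - 1L, ijk0[t, 3] + rv[t])
    dx2 <- (i - ax[t])^2
    dy2 <- (j - ay[t])^2
    dz2 <- (k - az[t])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2[t]
    occ[i + 1L, j + 1L, k + 1L] <- occ[i + 1L, j + 1L, k + 1L] | inside
  }
  lab <- flood_label(occ)
  comp <- tabulate(lab$labels, nbins = lab$n)
  interior <- which(seq_len(lab$n) != lab$exterior & comp >= min_voxels)
  sizes <- sort(comp[interior], decreasing = TRUE)
  structure(list(
    n_cavities = length(sizes),
    voxel_counts = sizes,
    volumes = sizes * grid_res^3,
    grid_res = grid_res, probe_radius = probe_radius,
    min_voxels = min_voxels
  ), class = "cavity_report")
}

#' @export
print.cavity_report <- function(x, ...) {
  cat("cavity_report: ", x$n_cavities, " interior cavities (grid ",
      x$grid_res, " A, probe ", x$probe_radius, " A)\n", sep = "")
  if (x$n_cavities > 0) {
    cat("volumes (A^3): ", paste(round(x$volumes, 1), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# 6-connected component labelling of the empty voxels of a 3D occupancy
# array, by vectorized frontier expansion. Returns integer labels (0 =
# occupied), the number of components, and the label of the exterior
# component (the one touching the array boundary; boundary-touching
# components are merged into one exterior label since the box is padded).
flood_label <- function(occ) {
  dims <- dim(occ)
  n <- prod(dims)
  labels <- integer(n)
  empty <- !as.vector(occ)
  sx <- 1L
  sy <- dims[1]
  sz <- dims[1] * dims[2]
  ix <- arrayInd(seq_len(n), dims)  # used to stop wrap-around at faces
  at_lo_x <- ix[, 1] == 1L;        at_hi_x <- ix[, 1] == dims[1]
  at_lo_y <- ix[, 2] == 1L;        at_hi_y <- ix[, 2] == dims[2]
  at_lo_z <- ix[, 3] == 1L;        at_hi_z <- ix[, 3] == dims[3]
  grow <- function(seed_idx, id) {
    frontier <- seed_idx[empty[seed_idx] & labels[seed_idx] == 0L]
    labels[frontier] <<- id
    while (length(frontier) > 0) {
      nb <- c(frontier[!at_hi_x[frontier]] + sx,
              frontier[!at_lo_x[frontier]] - sx,
              frontier[!at_hi_y[frontier]] + sy,
              frontier[!at_lo_y[frontier]] - sy,
              frontier[!at_hi_z[frontier]] + sz,
              frontier[!at_lo_z[frontier]] - sz)
      nb <- unique(nb[empty[nb] & labels[nb] == 0L])
      labels[nb] <<- id
      frontier <- nb
    }
  }
  boundary <- which((at_lo_x | at_hi_x | at_lo_y | at_hi_y |
                       at_lo_z | at_hi_z) & empty)
  next_id <- 0L
  exterior <- 0L
  if (length(boundary) > 0) {
    next_id <- 1L
    exterior <- 1L
    grow(boundary, 1L)
  }
  remaining <- which(empty & labels == 0L)
  while (length(remaining) > 0) {
    next_id <- next_id + 1L
    grow(remaining[1], next_id)
    remaining <- remaining[labels[remaining] == 0L]
  }
  list(labels = labels, n = next_id, exterior = exterior)
}

#' Molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water (18.0153 Da), in kDa.
#'
#' @param sequence One amino-acid sequence of standard residues.
#' @return Molecular weight in kDa.
#' @export
#' @examples
#' molecular_weight("GG")
molecular_weight <- function(sequence) {
  ch <- aa_chars(as_aa_character(sequence)[1])
  if (length(ch) == 0) stop("empty sequence")
  bad <- which(!(ch %in% amino_acids()))
  if (length(bad) > 0) {
    stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1])
  }
  (sum(.aa_residue_mass[ch]) + .water_mass) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge using the EMBOSS pKa set (N-terminus
#' 8.6, C-terminus 3.6, Cys 8.5, Asp 3.9, Glu 4.1, His 6.5, Lys 10.8,
#' Arg 12.5, Tyr 10.1). Monotonically non-increasing in pH.
#'
#' @param sequence One amino-acid sequence (>= 1 standard residue;
#'   non-standard residues are ignored for charge).
#' @param pH pH value(s).
#' @return Net charge, vectorized over `pH`.
#' @export
net_charge <- function(sequence, pH) {
  ch <- aa_chars(as_aa_character(sequence)[1])
  ch <- ch[ch %in% amino_acids()]
  if (length(ch) == 0) stop("no standard residues in sequence")
  counts <- c(Nterm = 1, Cterm = 1, table(ch)[c("C", "D", "E", "H", "K",
                                                "R", "Y")])
  counts[is.na(counts)] <- 0
  names(counts) <- c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y")
  pos <- c("Nterm", "H", "K", "R")
  neg <- c("Cterm", "C", "D", "E", "Y")
  vapply(pH, function(p) {
    sum(counts[pos] / (1 + 10^(p - .pka[pos]))) -
      sum(counts[neg] / (1 + 10^(.pka[neg] - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge()] vanishes, found by bisection on pH in
#' `[0, 14]` to `|charge| < 1e-4` (at most 60 iterations).
#'
#' @inheritParams net_charge
#' @return The pI.
#' @export
#' @examples
#' isoelectric_point("GG")  # termini only: (3.6 + 8.6) / 2
isoelectric_point <- function(sequence) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Tabulate structure metrics for a set of models
#'
#' One row per structure: atom and secondary-structure record counts, cavity
#' count, and (when sequences are supplied) molecular weight and pI.
#'
#' @param models Named list of `structure_model`s.
#' @param sequences Optional named character vector of the corresponding
#'   protein sequences.
#' @param ... Passed to [count_cavities()].
#' @return Data frame with columns `id`, `n_atoms`, `helix_records`,
#'   `sheet_records`, `n_cavities`, and optionally `mw_kda`, `pi`.
#' @export
structure_report <- function(models, sequences = NULL, ...) {
  stopifnot(is.list(models))
  ids <- names(models) %||% sprintf("model%d", seq_along(models))
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    cav <- count_cavities(m, ...)
    r <- data.frame(id = ids[i], n_atoms = nrow(m$atoms),
                    helix_records = m$helix_records,
                    sheet_records = m$sheet_records,
                    n_cavities = cav$n_cavities)
    if (!is.null(sequences) && ids[i] %in% names(sequences)) {
      r$mw_kda <- molecular_weight(sequences[[ids[i]]])
      r$pi <- isoelectric_point(sequences[[ids[i]]])
    }
    r
  })
  do.call(rbind, rows)
}

#' Compare cavity counts (or any counting metric) between groups
#'
#' Delegates to [kruskal_wallis()], the appropriate test for counting data.
#'
#' @param values Numeric vector of per-structure metrics (e.g. cavity
#'   counts).
#' @param groups Group label per structure.
#' @param n_perm Monte-Carlo permutations (default 1e5).
#' @param seed RNG seed.
#' @return A `kw_result` (see [kruskal_wallis()]).
#' @export
#' @examples
#' tab <- aspartic_peptidase_structures()
#' compare_structural_groups(tab$n_cavities, tab$group, n_perm = 999,
#'                           seed = 1)
compare_structural_groups <- function(values, groups, n_perm = 1e5,
                                      seed = NULL) {
  kruskal_wallis(values, groups, n_perm = n_perm, seed = seed)
}
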
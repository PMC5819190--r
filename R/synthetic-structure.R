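# Synthetic protein-like structures with a known number of interior voids.

#' Generate a structure with a known number of interior cavities
#'
#' Builds a solid slab of carbon atoms on a cubic lattice and embeds
#' `n_cavities` disjoint hollow spherical shells: for each cavity, slab atoms
#' within `shell_radius + atom_spacing` of the cavity center are removed and
#' replaced by a spherical shell of atoms at exactly `shell_radius` (Fibonacci
#' sphere, point spacing well below the probe-closable limit). The shell
#' interior is a solvent-inaccessible void whose free radius is exactly
#' `shell_radius - (r_C + probe)` up to discretization, which makes the
#' analytic interior volume available as ground truth.
#'
#' The lattice spacing must stay at or below 2.4 Angstrom so that walls are
#' watertight for the default carbon radius (1.70) plus probe (1.4): the
#' worst-case interstitial distance of a simple cubic lattice,
#' `spacing * sqrt(3) / 2`, then stays below 3.1.
#'
#' @param n_cavities Number of interior voids (>= 0).
#' @param shell_radius_A Shell radius in Angstrom; must exceed the closable
#'   limit `r_C + probe = 3.1` so an interior exists.
#' @param atom_spacing_A Cubic lattice spacing in Angstrom (<= 2.4).
#' @param seed Integer seed for the small positional jitter applied to slab
#'   atoms.
#' @param file Optional path; when given, the structure is also written as a
#'   minimal PDB file (ATOM records with the element column set).
#' @return A `structure_model` (see [read_pdb()]) with attribute `truth`
#'   holding `n_cavities`, the cavity centers, and the analytic interior
#'   volume per cavity.
#' @seealso [count_cavities()]
#' @export
#' @examples
#' s <- make_structure(1, shell_radius_A = 8, seed = 1)
#' attr(s, "truth")$n_cavities
make_structure <- function(n_cavities, shell_radius_A = 8,
                           atom_spacing_A = 1.8, seed = 1, file = NULL) {
  stopifnot(n_cavities >= 0)
  r_atom <- .vdw_radius[["C"]]
  closable <- r_atom + 1.4
  if (atom_spacing_A > 2.4) {
    stop("atom_spacing_A must be <= 2.4 Angstrom for watertight walls")
  }
  if (n_cavities > 0 && shell_radius_A <= closable + 1) {
    stop("shells of radius ", shell_radius_A,
         " have no probe-excluded interior (need > ", closable + 1, ")")
  }
  s <- atom_spacing_A
  wall <- 3 * s
  r <- shell_radius_A
  # cavity centers along x, spaced so shells are disjoint with full walls
  if (n_cavities > 0) {
    lx <- n_cavities * 2 * r + (n_cavities + 1) * wall
    ly <- 2 * r + 2 * wall
    centers <- cbind(wall + r + (seq_len(n_cavities) - 1) * (2 * r + wall),
                     ly / 2, ly / 2)
  } else {
    lx <- ly <- 6 * wall
    centers <- matrix(numeric(0), 0, 3)
  }
  gx <- seq(0, lx, by = s); gy <- seq(0, ly, by = s)
  lattice <- as.matrix(expand.grid(x = gx, y = gy, z = gy))
  xyz <- with_seed(seed, {
    lattice + matrix(runif(length(lattice), -0.05, 0.05), nrow(lattice))
  })
  if (n_cavities > 0) {
    keep <- rep(TRUE, nrow(xyz))
    shell_pts <- list()
    for (i in seq_len(n_cavities)) {
      d2 <- (xyz[, 1] - centers[i, 1])^2 + (xyz[, 2] - centers[i, 2])^2 +
        (xyz[, 3] - centers[i, 3])^2
      keep <- keep & d2 > (r + s)^2
      shell_pts[[i]] <- sweep(fibonacci_sphere(r, max_spacing = 1.6), 2,
                              centers[i, ], `+`)
    }
    xyz <- rbind(xyz[keep, , drop = FALSE], do.call(rbind, shell_pts))
  }
  n <- nrow(xyz)
  atoms <- data.frame(
    element = rep("C", n), resid = rep("UNK", n), chain = rep("A", n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep(r_atom, n)
  )
  model <- structure(list(atoms = atoms, helix_records = 0L,
                          sheet_records = 0L, source = "synthetic"),
                     class = "structure_model")
  r_free <- r - closable
  attr(model, "truth") <- list(
    n_cavities = as.integer(n_cavities), centers = centers,
    interior_radius = if (n_cavities > 0) r_free else numeric(0),
    interior_volume = if (n_cavities > 0) 4 / 3 * pi * r_free^3 else numeric(0)
  )
  if (!is.null(file)) write_structure_pdb(model, file)
  model
}

# Near-uniform points on a sphere of radius r with chord spacing <= max_spacing.
fibonacci_sphere <- function(r, max_spacing = 1.6) {
  n <- max(16L, ceiling(4 * pi * r^2 / (0.5 * max_spacing^2)))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta), r * cos(phi))
}

#' Write a structure model as a minimal PDB file
#'
#' Emits fixed-column ATOM records (occupancy 1.00, B-factor 0.00) with the
#' element symbol in columns 77-78, followed by END.
#'
#' @param model A `structure_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(model, file) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, paste0(" ", a$element), a$resid, a$chain,
    (seq_len(nrow(a)) - 1L) %% 9999 + 1L, a$x, a$y, a$z, 1, 0, a$element
  )
  writeLines(c(lines, "END"), file)
  invisible(file)
}
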
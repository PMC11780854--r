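#' Van der Waals radii used for accessibility calculations
#'
#' Standard heavy-atom radii in Angstrom: C 1.70, N 1.55, O 1.52, P 1.80.
#' Atoms classified as `other` have no default radius and require an
#' explicit override.
#'
#' @export
default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80)

# Deterministic golden-spiral lattice of n points on the unit sphere.
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 1L
  z <- 1 - (2 * k + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Map coordinates to a canonical frame (centroid at origin, principal
# axes as coordinate axes, signs fixed by the third moment, right-handed)
# so that the fixed test-point lattice sees the same geometry whatever
# rigid motion was applied to the input.
canonical_frame <- function(xyz) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(xyz) < 2L) return(xc)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  R <- ev$vectors
  for (k in 1:3) {
    s <- sum((xc %*% R[, k])^3)
    if (s < -1e-9) R[, k] <- -R[, k]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  xc %*% R
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' Places a deterministic golden-spiral lattice of test points on each
#' atom's solvent-expanded sphere (radius + probe) and counts the points
#' lying strictly inside no other atom's expanded sphere. The area is
#' `4 * pi * (r + probe)^2 * exposed / total`. The default 3 Angstrom
#' probe approximates the bulk of common probing reagents rather than a
#' water molecule. Because the buried test is strict (`< `, not `<=`),
#' exactly coincident spheres do not occlude each other. Coordinates are
#' first mapped to a canonical principal-axes frame, making the result
#' exactly invariant under rigid rotation and translation of the input.
#'
#' @param atoms Atom tibble as returned by [read_pdb_atoms()].
#' @param probe_radius Probe radius in Angstrom (default 3).
#' @param n_sphere_points Test points per atom (default 960).
#' @param radii Named vector of van der Waals radii; must cover every
#'   element present (add an `other` entry to admit unclassified atoms).
#' @return The input tibble with an added `sasa` column (Angstrom^2).
#' @export
shrake_rupley <- function(atoms, probe_radius = 3, n_sphere_points = 960L,
                          radii = default_vdw_radii) {
  if (nrow(atoms) < 1L) {
    abort("need at least one atom.", class = "probeval_validation_error")
  }
  missing <- setdiff(unique(atoms$element), names(radii))
  if (length(missing) > 0L) {
    abort(sprintf("no van der Waals radius for element '%s'; supply one via `radii`.",
                  missing[1]),
          class = "probeval_validation_error")
  }
  r_atom <- unname(radii[atoms$element]) + probe_radius
  xyz <- canonical_frame(cbind(atoms$x, atoms$y, atoms$z))
  pts <- golden_spiral_points(n_sphere_points)
  n_atoms <- nrow(atoms)
  area <- numeric(n_atoms)
  # pairwise centre distances for neighbour pruning
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    nb <- which(d2[i, ] < (r_atom[i] + r_atom)^2 & seq_len(n_atoms) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * r_atom[i]^2
      next
    }
    test <- pts * r_atom[i]
    test <- sweep(test, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      # strictly inside buries; the relative epsilon keeps points lying
      # exactly on a neighbouring sphere (e.g. coincident atoms) exposed
      exposed <- exposed & dj2 >= r_atom[j]^2 * (1 - 1e-9)
    }
    area[i] <- 4 * pi * r_atom[i]^2 * sum(exposed) / n_sphere_points
  }
  out <- atoms
  out$sasa <- area
  out
}

#' Per-residue absolute and relative solvent accessibility
#'
#' Absolute accessibility of a residue is the sum of its atoms' areas
#' computed in the full structural context. The relative value divides by
#' the same residue's area recomputed in isolation (all other residues
#' deleted), so an unocculted residue scores 1 and a fully buried one 0.
#' This isolated-residue normalisation is recorded here so users can
#' substitute fixed per-nucleotide maxima if preferred.
#'
#' @inheritParams shrake_rupley
#' @return A tibble with columns `chain`, `residue_index`, `residue_name`,
#'   `absolute_sasa` and `relative_sasa` (0 when the isolated reference
#'   area is 0; may exceed 1 by quadrature noise only).
#' @export
residue_accessibility <- function(atoms, probe_radius = 3,
                                  n_sphere_points = 960L,
                                  radii = default_vdw_radii) {
  full <- shrake_rupley(atoms, probe_radius, n_sphere_points, radii)
  key <- paste(full$chain, full$residue_index, sep = "\r")
  per_res <- full |>
    group_by(.data$chain, .data$residue_index) |>
    summarise(residue_name = .data$residue_name[1],
              absolute_sasa = sum(.data$sasa), .groups = "drop")
  ref <- vapply(paste(per_res$chain, per_res$residue_index, sep = "\r"),
                function(k) {
                  sub <- atoms[key == k, , drop = FALSE]
                  sum(shrake_rupley(sub, probe_radius, n_sphere_points,
                                    radii)$sasa)
                }, numeric(1))
  ref <- unname(ref)
  per_res |>
    mutate(relative_sasa = unname(ifelse(ref > 0, .data$absolute_sasa / ref, 0))) |>
    arrange(.data$chain, .data$residue_index)
}
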
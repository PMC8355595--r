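# Per-nucleotide structural geometry: 2'-OH accessibility and sugar pucker.

#' Van der Waals radii used for surface-area calculations
#'
#' Fixed published values (Angstrom); elements not listed fall back to the
#' carbon radius.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
}

#' Ligand-accessible surface area of each 2'-hydroxyl oxygen
#'
#' Shrake-Rupley surface sampling of the O2' atom of every nucleotide
#' against all heavy atoms of the structure, with a spherical probe ("bead")
#' representing the SHAPE reagent. Sphere points come from a deterministic
#' golden-section spiral, so results are bit-stable across runs at a fixed
#' point count. Nucleotides lacking an O2' atom (e.g. backbone-only modified
#' residues missing it, or DNA-like inputs) are flagged missing rather than
#' reported as zero.
#'
#' @param x An [rna_structure].
#' @param bead_radius Probe radius in Angstrom (default 2.0).
#' @param n_points Number of sphere sample points per atom (default 960).
#' @param radii Named vdW radius table, see [vdw_radii()].
#' @return Tibble with columns `res_index`, `sasa` (Angstrom^2, NA when
#'   missing), `missing`.
#' @export
sasa_2oh <- function(x, bead_radius = 2.0, n_points = 960,
                     radii = vdw_radii()) {
  stopifnot(bead_radius > 0, n_points >= 12)
  nt <- nucleotides(x)
  atoms <- x$atoms
  coords <- atom_xyz(atoms)
  r_atom <- unname(radii[atoms$element])
  r_atom[is.na(r_atom)] <- radii[["C"]]
  pts <- sphere_points(n_points)
  r_o <- radii[["O"]]
  out <- tibble(res_index = nt$res_index, sasa = NA_real_, missing = TRUE)
  for (k in seq_len(nrow(nt))) {
    row <- which(atoms$res_index == nt$res_index[k] & atoms$atom == "O2'")
    if (length(row) == 0) next
    center <- coords[row[1], ]
    radius <- r_o + bead_radius
    # neighbors whose expanded spheres can reach the probe surface
    d2 <- (coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
      (coords[, 3] - center[3])^2
    reach <- (radius + r_atom + bead_radius)^2
    nb <- which(d2 <= reach & seq_len(nrow(coords)) != row[1])
    if (length(nb) == 0) {
      frac <- 1
    } else {
      surf <- sweep(pts * radius, 2, center, `+`)
      nb_xyz <- coords[nb, , drop = FALSE]
      nb_r2 <- (r_atom[nb] + bead_radius)^2
      # squared distances surface-point x neighbor
      dm <- outer(rowSums(surf^2), rowSums(nb_xyz^2), `+`) -
        2 * surf %*% t(nb_xyz)
      buried <- rowSums(sweep(dm, 2, nb_r2, `<`)) > 0
      frac <- mean(!buried)
    }
    out$sasa[k] <- frac * 4 * pi * radius^2
    out$missing[k] <- FALSE
  }
  attr(out, "bead_radius") <- bead_radius
  attr(out, "n_points") <- n_points
  out
}

#' Pseudorotation phase from the five ribose ring torsions
#'
#' Altona-Sundaralingam convention with nu2 (C1'-C2'-C3'-C4') as the
#' reference torsion; the quadrant is resolved with a two-argument
#' arctangent, and the amplitude is recovered robustly as
#' `sqrt(nu2^2 + ((nu4 + nu1 - nu3 - nu0) / (2 (sin 36 + sin 72)))^2)`.
#'
#' @param nu Numeric vector of the five ring torsions `nu0..nu4` in degrees.
#' @return List with `P` (degrees in `[0, 360)`, NA for a planar ring),
#'   `nu_max` (degrees, >= 0) and `pucker_class`.
#' @export
pseudorotation_from_torsions <- function(nu) {
  stopifnot(length(nu) == 5)
  denom <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  s <- num / (2 * (sin(deg2rad(36)) + sin(deg2rad(72))))  # = nu_max sin(P)
  nu_max <- sqrt(nu[3]^2 + s^2)
  if (nu_max < 1e-9) {
    return(list(P = NA_real_, nu_max = 0, pucker_class = "planar/undefined"))
  }
  P <- rad2deg(atan2(num, denom)) %% 360
  list(P = P, nu_max = nu_max, pucker_class = pucker_class(P))
}

#' Pucker class from the pseudorotation phase
#'
#' 36-degree sectors of the pseudorotation wheel: C3'-endo at `[0, 36)`,
#' C2'-endo at `[144, 180)`, and so on around the cycle.
#'
#' @param P Phase angle in degrees (vectorized).
#' @return Character vector of class labels.
#' @export
pucker_class <- function(P) {
  labels <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
              "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")
  out <- rep(NA_character_, length(P))
  ok <- !is.na(P)
  out[ok] <- labels[floor((P[ok] %% 360) / 36) + 1]
  out
}

#' Ribose pseudorotation per nucleotide
#'
#' Computes the five ring torsions from the coordinates of C1'-C4' and O4'
#' and converts them to pseudorotation phase, amplitude and pucker class.
#' Nucleotides with any ring atom missing are flagged (their sugar factor
#' defaults to 1 downstream).
#'
#' @param x An [rna_structure].
#' @return Tibble with columns `res_index`, `P`, `nu_max`, `pucker_class`,
#'   `missing`.
#' @export
pseudorotation <- function(x) {
  nt <- nucleotides(x)
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  out <- tibble(res_index = nt$res_index, P = NA_real_, nu_max = NA_real_,
                pucker_class = NA_character_, missing = TRUE)
  for (k in seq_len(nrow(nt))) {
    idx <- nt$res_index[k]
    pos <- lapply(ring, function(a) residue_atom(x$atoms, idx, a))
    if (any(vapply(pos, is.null, logical(1)))) next
    names(pos) <- ring
    nu <- c(
      point_torsion(pos[["C4'"]], pos[["O4'"]], pos[["C1'"]], pos[["C2'"]]),
      point_torsion(pos[["O4'"]], pos[["C1'"]], pos[["C2'"]], pos[["C3'"]]),
      point_torsion(pos[["C1'"]], pos[["C2'"]], pos[["C3'"]], pos[["C4'"]]),
      point_torsion(pos[["C2'"]], pos[["C3'"]], pos[["C4'"]], pos[["O4'"]]),
      point_torsion(pos[["C3'"]], pos[["C4'"]], pos[["O4'"]], pos[["C1'"]]))
    ps <- pseudorotation_from_torsions(nu)
    out$P[k] <- ps$P
    out$nu_max[k] <- ps$nu_max
    out$pucker_class[k] <- ps$pucker_class
    out$missing[k] <- FALSE
  }
  out
}

#' Sugar-pucker correction factor
#'
#' Multiplicative reactivity correction looked up from the configured
#' pucker-class map; classes absent from the map (and missing puckers) get
#' factor 1.
#'
#' @param pucker Tibble from [pseudorotation()].
#' @param params Model parameters, see [default_params()].
#' @return Numeric vector of factors, one per nucleotide.
#' @export
sugar_factor <- function(pucker, params) {
  map <- params$f_sug
  out <- rep(1, nrow(pucker))
  for (k in seq_len(nrow(pucker))) {
    cls <- pucker$pucker_class[k]
    if (pucker$missing[k] || is.na(cls)) next
    if (!is.null(map[[cls]])) {
      out[k] <- map[[cls]]
    } else if (!is.null(map[["other"]])) {
      out[k] <- map[["other"]]
    }
  }
  out
}
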
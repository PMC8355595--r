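# Shared fixtures (built once per test run) and small PDB text utilities.

fx <- new.env()
fx$duplex_gggg <- build_duplex("GGGG")
fx$hairpin3 <- build_hairpin(3, "GAAA")
fx$hairpin4 <- build_hairpin(4, "GAAA")

# Format one fixed-width PDB ATOM/HETATM record.
pdb_record <- function(record = "ATOM", serial, name, resname, chain, resno,
                       x, y, z, altloc = " ", element = NULL) {
  if (is.null(element)) {
    element <- toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
  }
  name_field <- if (nchar(name) < 4) {
    sprintf(" %-3s", name)
  } else {
    name
  }
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, altloc, resname, chain, resno,
          x, y, z, 1.00, 0.00, element)
}

# PDB text of a structure plus arbitrary extra records appended before END.
pdb_text_with <- function(structure, extra = character(0)) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  write_rna_pdb(structure, tf)
  lines <- readLines(tf)
  c(setdiff(lines, "END"), extra, "END")
}

# Water / ion / protein / DNA decoration records for cleanup tests.
decoration_records <- function(start_serial = 9000, chain = "X") {
  recs <- character(0)
  s <- start_serial
  for (w in 1:5) {
    recs <- c(recs, pdb_record("HETATM", s, "O", "HOH", chain, 500 + w,
                               50 + w, 50, 50, element = "O"))
    s <- s + 1
  }
  recs <- c(recs,
            pdb_record("HETATM", s, "MG", "MG", chain, 601, 60, 60, 60,
                       element = "MG"),
            pdb_record("ATOM", s + 1, "N", "ALA", "P", 1, 70, 70, 70),
            pdb_record("ATOM", s + 2, "CA", "ALA", "P", 1, 71, 70, 70),
            pdb_record("ATOM", s + 3, "C", "ALA", "P", 1, 72, 70, 70),
            pdb_record("ATOM", s + 4, "O", "ALA", "P", 1, 72, 71, 70),
            # DNA residue: no O2', name-based DNA code
            pdb_record("ATOM", s + 5, "C1'", "DA", "D", 1, 80, 80, 80),
            pdb_record("ATOM", s + 6, "N9", "DA", "D", 1, 81, 80, 80),
            pdb_record("ATOM", s + 7, "C4'", "DA", "D", 1, 80, 81, 80))
  recs
}

# Independent quaternion-based superposition (Horn 1987) used as the RMSD
# oracle: returns RMSD of b onto a after optimal rotation + translation.
quaternion_rmsd <- function(ma, mb) {
  ca <- colMeans(ma)
  cb <- colMeans(mb)
  a <- sweep(ma, 2, ca)
  b <- sweep(mb, 2, cb)
  m <- t(b) %*% a
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4, byrow = TRUE)
  ev <- eigen(k, symmetric = TRUE)
  q <- ev$vectors[, 1]
  rot <- matrix(c(
    q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2, 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2,
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2), 3, 3, byrow = TRUE)
  b_rot <- b %*% t(rot)
  sqrt(mean(rowSums((a - b_rot)^2)))
}

# Apply a rigid transform (rotation matrix + translation) to a structure.
transform_structure <- function(x, rot, trans = c(0, 0, 0)) {
  xyz <- as.matrix(x$atoms[, c("x", "y", "z")]) %*% t(rot)
  x$atoms$x <- xyz[, 1] + trans[1]
  x$atoms$y <- xyz[, 2] + trans[2]
  x$atoms$z <- xyz[, 3] + trans[3]
  x
}

rotation_about_z <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

seeded_random_rotation <- function(seed) {
  q <- withr::with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# Minimal bare structure from an atom spec list for constructed geometry
# tests: each element list(res = i, atom = "O2'", el = "O", xyz = c(...)).
bare_structure <- function(spec, resname = "G") {
  rows <- lapply(seq_along(spec), function(k) {
    s <- spec[[k]]
    tibble::tibble(chain = "A", resno = s$res, resname = resname,
                   res_index = s$res, atom = s$atom, element = s$el,
                   x = s$xyz[1], y = s$xyz[2], z = s$xyz[3],
                   is_modified = FALSE)
  })
  rna_structure(dplyr::bind_rows(rows), source_name = "bare")
}

# A guanine base (ring atoms only) translated to `offset`, as an atom spec.
template_atoms_at <- function(offset, res = 1L) {
  b <- shapesieve:::.aform$bases$G
  lapply(rownames(b), function(a) {
    list(res = res, atom = a,
         el = toupper(substr(a, 1, 1)),
         xyz = b[a, ] + offset)
  })
}

two_residue_structure <- function(spec1, spec2) {
  spec2 <- lapply(spec2, function(s) { s$res <- 2L; s })
  bare_structure(c(spec1, spec2))
}
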
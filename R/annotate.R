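# Geometric annotation of base pairs and stacking contacts.
#
# The detectors operate purely on heavy-atom coordinates. Gates are
# configurable; the defaults reproduce classic annotation geometry:
#   pairs:  centroid pre-filter, >=1 polar heavy-atom contact between base
#           edges, near-coplanar base planes, small vertical separation.
#   stacks: ring-centroid distance window, near-parallel plane normals,
#           bounded lateral (in-plane) centroid offset.

base_ring_atoms <- function(base) {
  if (base %in% c("A", "G")) {
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  } else {
    c("N1", "C2", "N3", "C4", "C5", "C6")
  }
}

glycosidic_atom <- function(base) if (base %in% c("A", "G")) "N9" else "N1"

# Edge membership of polar base atoms (plus O2' on the sugar edge).
base_edge_atoms <- function(base) {
  switch(base,
    A = list(W = c("N1", "N6"), H = c("N7", "N6"), S = c("N3", "O2'")),
    G = list(W = c("N1", "N2", "O6"), H = c("N7", "O6"), S = c("N3", "N2", "O2'")),
    C = list(W = c("N3", "N4", "O2"), H = c("N4"), S = c("O2", "O2'")),
    U = list(W = c("N3", "O4", "O2"), H = c("O4"), S = c("O2", "O2'")),
    list(W = character(0), H = character(0), S = character(0)))
}

default_pair_gates <- function() {
  list(max_origin_dist = 15, max_contact = 3.4,
       max_normal_angle = 65, max_vertical_sep = 2.5)
}

default_stack_gates <- function() {
  list(min_centroid_dist = 2.0, max_centroid_dist = 5.5,
       max_normal_angle = 30, max_offset = 3.5)
}

# Per-residue base geometry: ring centroid, plane normal, polar edge atoms.
base_geometry <- function(x) {
  nt <- nucleotides(x)
  atoms <- x$atoms
  ri <- atoms$res_index
  name <- atoms$atom
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  polar_ok <- atoms$element %in% c("N", "O") &
    !name %in% c("P", "OP1", "OP2", "O5'", "O4'", "O3'")
  out <- vector("list", nrow(nt))
  for (k in seq_len(nrow(nt))) {
    idx <- nt$res_index[k]
    base <- nt$base[k]
    rows <- which(ri == idx)
    ring_rows <- rows[name[rows] %in% base_ring_atoms(base)]
    if (length(ring_rows) < 3 || nt$is_modified[k]) next
    m <- xyz[ring_rows, , drop = FALSE]
    polar_rows <- rows[polar_ok[rows]]
    gly <- rows[name[rows] == glycosidic_atom(base)]
    c1 <- rows[name[rows] == "C1'"]
    out[[k]] <- list(
      res_index = idx, base = base,
      centroid = colMeans(m), normal = plane_normal(m),
      ring = m,
      polar_xyz = xyz[polar_rows, , drop = FALSE],
      polar_atom = name[polar_rows],
      n_gly = if (length(gly) > 0) xyz[gly[1], ] else NULL,
      c1p = if (length(c1) > 0) xyz[c1[1], ] else NULL)
  }
  names(out) <- as.character(nt$res_index)
  out[!vapply(out, is.null, logical(1))]
}

#' Detect base pairs from 3D coordinates
#'
#' Candidate pairs pass a ring-centroid distance pre-filter, must show at
#' least one polar (N/O) heavy-atom contact between base edges within
#' `max_contact`, near-coplanar base planes (`max_normal_angle`) and a small
#' mutual out-of-plane separation (`max_vertical_sep`). Each detected pair is
#' classified by interacting edges (Watson-Crick `W`, Hoogsteen `H`, sugar
#' `S`) and glycosidic orientation (`cis`/`trans`); `cWW` pairs of AU, GC or
#' GU combinations are flagged canonical. Residues whose base atoms are
#' missing (e.g. modified residues kept as backbone) are skipped with a
#' warning.
#'
#' @param x An [rna_structure].
#' @param gates List of geometric gates; see `default_pair_gates()` in the
#'   model parameters.
#' @return Tibble with columns `i`, `j` (`i < j`, 1-based nucleotide
#'   indices), `base_i`, `base_j`, `edge_i`, `edge_j`, `orientation`,
#'   `pair_type` (e.g. `"cWW"`), `is_canonical`, `n_contacts`,
#'   `min_contact`, `score` (sum of contact distances; lower = tighter).
#' @export
detect_base_pairs <- function(x, gates = default_pair_gates()) {
  geo <- base_geometry(x)
  nt <- nucleotides(x)
  skipped <- setdiff(nt$res_index[!nt$is_modified], as.integer(names(geo)))
  if (length(skipped) > 0) {
    warn(paste0("residues without base atoms skipped in pair detection: ",
                paste(skipped, collapse = ", ")))
  }
  empty <- tibble(i = integer(0), j = integer(0),
                  base_i = character(0), base_j = character(0),
                  edge_i = character(0), edge_j = character(0),
                  orientation = character(0), pair_type = character(0),
                  is_canonical = logical(0), n_contacts = integer(0),
                  min_contact = numeric(0), score = numeric(0))
  if (length(geo) < 2) return(empty)
  idx <- as.integer(names(geo))
  cents <- t(vapply(geo, function(g) g$centroid, numeric(3)))
  rows <- list()
  for (a in seq_len(length(geo) - 1)) {
    for (b in (a + 1):length(geo)) {
      d <- vec_norm(cents[a, ] - cents[b, ])
      if (d > gates$max_origin_dist) next
      pr <- classify_pair(geo[[a]], geo[[b]], gates)
      if (is.null(pr)) next
      rows[[length(rows) + 1]] <- c(
        list(i = idx[a], j = idx[b],
             base_i = geo[[a]]$base, base_j = geo[[b]]$base), pr)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- as_tibble(do.call(rbind.data.frame, rows))
  arrange(out, .data$i, .data$j)
}

classify_pair <- function(gi, gj, gates) {
  # coplanarity
  ang <- rad2deg(acos(pmin(1, abs(sum(gi$normal * gj$normal)))))
  if (ang > gates$max_normal_angle) return(NULL)
  dvec <- gj$centroid - gi$centroid
  vi <- abs(sum(dvec * gi$normal))
  vj <- abs(sum(dvec * gj$normal))
  if (vi > gates$max_vertical_sep || vj > gates$max_vertical_sep) return(NULL)

  # polar-polar contacts between the two bases
  pi_xyz <- gi$polar_xyz
  pj_xyz <- gj$polar_xyz
  if (nrow(pi_xyz) == 0 || nrow(pj_xyz) == 0) return(NULL)
  dm <- sqrt(pmax(outer(rowSums(pi_xyz^2), rowSums(pj_xyz^2), `+`) -
                    2 * pi_xyz %*% t(pj_xyz), 0))
  hits <- which(dm <= gates$max_contact, arr.ind = TRUE)
  if (nrow(hits) == 0) return(NULL)
  contact_ai <- gi$polar_atom[hits[, 1]]
  contact_aj <- gj$polar_atom[hits[, 2]]
  contact_d <- dm[hits]

  edge_i <- assign_edge(contact_ai, contact_d, gi$base)
  edge_j <- assign_edge(contact_aj, contact_d, gj$base)
  if (is.null(edge_i) || is.null(edge_j)) return(NULL)

  orientation <- pair_orientation(gi, gj)
  pair_type <- paste0(substr(orientation, 1, 1), edge_i, edge_j)
  combo <- paste0(gi$base, gj$base)
  canonical <- pair_type == "cWW" &&
    combo %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  list(edge_i = edge_i, edge_j = edge_j, orientation = orientation,
       pair_type = pair_type, is_canonical = canonical,
       n_contacts = length(contact_d), min_contact = min(contact_d),
       score = sum(contact_d))
}

# Vote for the interacting edge: inverse-distance-weighted membership of the
# contacting atoms; ties resolved W > H > S.
assign_edge <- function(atoms, dists, base) {
  edges <- base_edge_atoms(base)
  votes <- c(W = 0, H = 0, S = 0)
  for (k in seq_along(atoms)) {
    for (e in names(edges)) {
      if (atoms[k] %in% edges[[e]]) votes[e] <- votes[e] + 1 / dists[k]
    }
  }
  if (all(votes == 0)) return(NULL)
  names(votes)[which.max(votes)]
}

# cis / trans from the glycosidic-bond orientation: project the two
# C1'-glycosidic-N vectors onto the mean base plane and compare their sides
# of the line joining the glycosidic nitrogens.
pair_orientation <- function(gi, gj) {
  if (is.null(gi$n_gly) || is.null(gj$n_gly) ||
      is.null(gi$c1p) || is.null(gj$c1p)) {
    return("cis")
  }
  nmean <- vec_unit(gi$normal + (if (sum(gi$normal * gj$normal) < 0) -1 else 1) * gj$normal)
  proj <- function(v) v - sum(v * nmean) * nmean
  d <- proj(gj$n_gly - gi$n_gly)
  vi <- proj(gi$c1p - gi$n_gly)
  vj <- proj(gj$c1p - gj$n_gly)
  si <- sum(vec_cross(d, vi) * nmean)
  sj <- sum(vec_cross(d, vj) * nmean)
  if (si * sj >= 0) "cis" else "trans"
}

#' Detect base-stacking contacts
#'
#' Two bases stack when their ring centroids lie within a distance window,
#' their plane normals are near-parallel, and the lateral (in-plane) offset
#' of one centroid projected onto the other's plane is small. Contacts are
#' stored symmetrically: each contact appears once per partner with the
#' partner's polarity relative to that nucleotide (`"5p"` when the partner
#' precedes it along the chain, `"3p"` when it follows).
#'
#' @param x An [rna_structure].
#' @param gates List of gates; see `default_stack_gates()`.
#' @return Tibble with columns `i` (nucleotide), `k` (partner), `polarity`
#'   (`"5p"`/`"3p"` of the partner relative to `i`), `base_i`, `base_k`,
#'   `centroid_dist`, `normal_angle`, `offset`.
#' @export
detect_stacking <- function(x, gates = default_stack_gates()) {
  geo <- base_geometry(x)
  empty <- tibble(i = integer(0), k = integer(0), polarity = character(0),
                  base_i = character(0), base_k = character(0),
                  centroid_dist = numeric(0), normal_angle = numeric(0),
                  offset = numeric(0))
  if (length(geo) < 2) return(empty)
  idx <- as.integer(names(geo))
  rows <- list()
  for (a in seq_len(length(geo) - 1)) {
    for (b in (a + 1):length(geo)) {
      gi <- geo[[a]]; gj <- geo[[b]]
      d <- vec_norm(gj$centroid - gi$centroid)
      if (d < gates$min_centroid_dist || d > gates$max_centroid_dist) next
      ang <- rad2deg(acos(pmin(1, abs(sum(gi$normal * gj$normal)))))
      if (ang > gates$max_normal_angle) next
      dvec <- gj$centroid - gi$centroid
      off_i <- vec_norm(dvec - sum(dvec * gi$normal) * gi$normal)
      off_j <- vec_norm(dvec - sum(dvec * gj$normal) * gj$normal)
      off <- min(off_i, off_j)
      if (off > gates$max_offset) next
      rows[[length(rows) + 1]] <- data.frame(
        i = c(idx[a], idx[b]), k = c(idx[b], idx[a]),
        polarity = c("3p", "5p"),
        base_i = c(gi$base, gj$base), base_k = c(gj$base, gi$base),
        centroid_dist = d, normal_angle = ang, offset = off)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- as_tibble(do.call(rbind, rows))
  arrange(out, .data$i, .data$k)
}

#' Extract the secondary (2D) structure from detected pairs
#'
#' Keeps canonical pairs only, resolves multiplets (a base in more than one
#' canonical pair) by retaining the pair with the best (lowest) geometric
#' score, and assigns pseudoknot bracket tiers: tier 1 is a maximum
#' non-crossing subset (dynamic programming), subsequent tiers are assigned
#' greedily from the remainder.
#'
#' @param pairs Tibble from [detect_base_pairs()] (or any tibble with
#'   columns `i`, `j`, `is_canonical`, optionally `score`).
#' @param length Number of nucleotides.
#' @return An object of class `rna_secondary_structure`: list with `length`,
#'   `paired_with` (integer vector, NA when unpaired), `tier` (integer per
#'   pair tier or NA), and `dot_bracket`.
#' @export
extract_secondary_structure <- function(pairs, length) {
  n <- as.integer(length)
  paired_with <- rep(NA_integer_, n)
  tier <- rep(NA_integer_, n)
  cp <- pairs |> filter(.data$is_canonical)
  if (!"score" %in% names(cp)) cp$score <- 0
  cp <- cp |> arrange(.data$score)
  # multiplet resolution: best score first, then greedy exclusivity
  used <- logical(n)
  keep <- logical(nrow(cp))
  for (r in seq_len(nrow(cp))) {
    i <- cp$i[r]; j <- cp$j[r]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      keep[r] <- TRUE
    }
  }
  cp <- cp[keep, , drop = FALSE]
  arcs <- cp |> select("i", "j") |> arrange(.data$i)

  openers <- c("(", "[", "{", "<")
  closers <- c(")", "]", "}", ">")
  db <- rep(".", n)
  tier_of_pair <- integer(nrow(arcs))
  remaining <- seq_len(nrow(arcs))
  level <- 0L
  while (length(remaining) > 0 && level < 4L) {
    level <- level + 1L
    sel <- max_noncrossing_subset(arcs[remaining, , drop = FALSE])
    chosen <- remaining[sel]
    tier_of_pair[chosen] <- level
    for (r in chosen) {
      db[arcs$i[r]] <- openers[level]
      db[arcs$j[r]] <- closers[level]
    }
    remaining <- setdiff(remaining, chosen)
  }
  for (r in seq_len(nrow(arcs))) {
    paired_with[arcs$i[r]] <- arcs$j[r]
    paired_with[arcs$j[r]] <- arcs$i[r]
    tier[arcs$i[r]] <- tier_of_pair[r]
    tier[arcs$j[r]] <- tier_of_pair[r]
  }
  structure(
    list(length = n, paired_with = paired_with, tier = tier,
         dot_bracket = paste(db, collapse = "")),
    class = "rna_secondary_structure")
}

#' @export
print.rna_secondary_structure <- function(x, ...) {
  cat("<rna_secondary_structure> length ", x$length, ", ",
      sum(!is.na(x$paired_with)) / 2, " pairs\n", sep = "")
  cat("  ", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

# Maximum non-crossing subset of arcs by interval dynamic programming.
# Returns indices (into `arcs` rows) of one maximum subset.
max_noncrossing_subset <- function(arcs) {
  m <- nrow(arcs)
  if (m == 0) return(integer(0))
  if (m == 1) return(1L)
  pos <- sort(unique(c(arcs$i, arcs$j)))
  np <- length(pos)
  ai <- match(arcs$i, pos)
  aj <- match(arcs$j, pos)
  arc_at <- vector("list", np)
  for (r in seq_len(m)) arc_at[[ai[r]]] <- c(arc_at[[ai[r]]], r)
  dp <- matrix(0L, np, np)
  choice <- matrix(0L, np, np)   # 0 = skip i, r > 0 = use arc r
  for (span in 1:(np - 1)) {
    for (i in 1:(np - span)) {
      j <- i + span
      best <- dp[i + 1, j]
      bc <- 0L
      for (r in arc_at[[i]]) {
        k <- aj[r]
        if (k > j) next
        v <- 1L +
          (if (k - 1 >= i + 1) dp[i + 1, k - 1] else 0L) +
          (if (j >= k + 1) dp[k + 1, j] else 0L)
        if (v > best) { best <- v; bc <- r }
      }
      dp[i, j] <- best
      choice[i, j] <- bc
    }
  }
  sel <- integer(0)
  stack <- list(c(1L, np))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j + 1 || i > np) next
    if (i == j) next
    r <- choice[i, j]
    if (r == 0L) {
      if (i + 1 <= j) stack[[length(stack) + 1]] <- c(i + 1L, j)
    } else {
      sel <- c(sel, r)
      k <- aj[r]
      if (i + 1 <= k - 1) stack[[length(stack) + 1]] <- c(i + 1L, k - 1L)
      if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1L, j)
    }
  }
  sort(sel)
}

#' Dot-bracket string of a secondary structure
#'
#' @param ss An `rna_secondary_structure`.
#' @return The dot-bracket string (tiers `()`, `[]`, `{}`, `<>`).
#' @export
dot_bracket <- function(ss) {
  stopifnot(inherits(ss, "rna_secondary_structure"))
  ss$dot_bracket
}
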
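# Exact-coordinate RNA fixture generation.
#
# Ideal A-form geometry is produced by stacking the frozen residue template
# (see aform-template.R) along a helix (default twist 32.7 deg, rise 2.81 A)
# and mating the complementary strand through the standard pair-frame flip
# (x, -y, -z). G-U pairs get a proper wobble: the uracil base slides
# in-plane until the two wobble hydrogen bonds (G N1-U O2, G O6-U N3) reach
# 2.85 A. Hairpin loops and single-stranded tails are grown residue by
# residue along a smooth outward arc so the backbone stays near-bonded and
# the splayed bases make no base-base contacts.

wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

is_valid_pair <- function(b1, b2) {
  paste0(b1, b2) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

reverse_complement <- function(seq_chars) {
  rev(unname(wc_partner[seq_chars]))
}

# Template residue (strand 1, pair frame): atoms tibble with names/elements.
template_residue <- function(base) {
  stopifnot(base %in% c("A", "U", "G", "C"))
  b <- .aform$bases[[base]]
  xyz <- rbind(.aform$sugar, `C1'` = .aform$c1p, b)
  tibble(
    atom = rownames(xyz),
    element = toupper(substr(gsub("[^A-Za-z]", "", rownames(xyz)), 1, 1)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

.wobble_cache <- new.env(parent = emptyenv())

# In-plane wobble slide for the uracil base of a G-U pair, solved
# deterministically from the two target hydrogen-bond lengths (memoized).
wobble_shift <- function(u_flipped = TRUE) {
  key <- if (u_flipped) "flipped" else "plain"
  if (!is.null(.wobble_cache[[key]])) return(.wobble_cache[[key]])
  g <- .aform$bases$G
  u <- .aform$bases$U
  flip <- function(m) { m[, 2] <- -m[, 2]; m[, 3] <- -m[, 3]; m }
  uu <- if (u_flipped) flip(u) else u
  gg <- if (u_flipped) g else flip(g)
  target <- function(t) {
    o2 <- uu["O2", 1:2] + t
    n3 <- uu["N3", 1:2] + t
    # small pull toward zero shift selects the physical (near) branch of
    # the two-constraint solution
    (vec_norm(c(o2, 0) - gg["N1", ]) - 2.85)^2 +
      (vec_norm(c(n3, 0) - gg["O6", ]) - 2.85)^2 +
      0.02 * sum(t^2)
  }
  opt <- optim(c(0.5, 0.8), target, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  .wobble_cache[[key]] <- opt$par
  opt$par
}

# Place template coordinates at helical step `pair_idx` (0-based).
# strand 2 is flipped through the pair frame before the helical transform.
place_helical <- function(res_tbl, pair_idx, strand = 1L,
                          twist = .aform$twist, rise = .aform$rise) {
  xyz <- as.matrix(res_tbl[, c("x", "y", "z")])
  if (strand == 2L) {
    xyz[, 2] <- -xyz[, 2]
    xyz[, 3] <- -xyz[, 3]
  }
  xyz <- sweep(xyz, 2, c(.aform$dx, 0, 0))
  xyz <- xyz %*% t(rotation_z(pair_idx * twist))
  xyz <- sweep(xyz, 2, c(0, 0, pair_idx * rise), `+`)
  res_tbl$x <- xyz[, 1]; res_tbl$y <- xyz[, 2]; res_tbl$z <- xyz[, 3]
  res_tbl
}

# Apply the wobble slide to the base atoms (sugar untouched) of a U that
# faces a G. Operates in the pair frame, before the helical transform.
apply_wobble <- function(res_tbl, strand) {
  shift <- wobble_shift(u_flipped = (strand == 2L))
  # the shift is solved in the final pair-frame orientation; strand-2
  # residues are flipped (y -> -y) after this step, so pre-negate y
  if (strand == 2L) shift[2] <- -shift[2]
  base_rows <- res_tbl$atom %in% rownames(.aform$bases$U)
  res_tbl$x[base_rows] <- res_tbl$x[base_rows] + shift[1]
  res_tbl$y[base_rows] <- res_tbl$y[base_rows] + shift[2]
  res_tbl
}

assemble_structure <- function(res_list, chains, resnos, resnames,
                               source_name) {
  atoms <- bind_rows(lapply(seq_along(res_list), function(k) {
    res_list[[k]] |>
      mutate(chain = chains[k], resno = resnos[k], resname = resnames[k],
             res_index = k, is_modified = FALSE)
  }))
  rna_structure(atoms |>
                  select("chain", "resno", "resname", "res_index", "atom",
                         "element", "x", "y", "z", "is_modified"),
                model_id = 1L, source_name = source_name)
}

#' Build an ideal A-form RNA duplex
#'
#' Two complementary strands (Watson-Crick plus G-U wobble) as chains A and
#' B. Strand 2 defaults to the reverse complement of strand 1. Both strands
#' are listed 5' to 3'.
#'
#' @param seq1 Strand-1 sequence (string of A/U/G/C).
#' @param seq2 Optional strand-2 sequence (5' to 3'); must be pairwise
#'   complementary to strand 1 under WC + wobble rules.
#' @param rise Helical rise per base pair, Angstrom.
#' @param twist Helical twist per base pair, degrees.
#' @return An [rna_structure] with an attribute `dot_bracket` recording the
#'   construction's pairing (`&`-separated chains).
#' @export
build_duplex <- function(seq1, seq2 = NULL,
                         rise = .aform$rise, twist = .aform$twist) {
  s1 <- strsplit(toupper(seq1), "")[[1]]
  n <- length(s1)
  stopifnot(n >= 1, all(s1 %in% c("A", "U", "G", "C")))
  s2 <- if (is.null(seq2)) reverse_complement(s1) else strsplit(toupper(seq2), "")[[1]]
  if (length(s2) != n) abort("strand lengths differ")
  for (k in seq_len(n)) {
    if (!is_valid_pair(s1[k], s2[n - k + 1])) {
      abort(paste0("strands are not complementary at pair ", k, " (",
                   s1[k], "-", s2[n - k + 1], ")"))
    }
  }
  res <- vector("list", 2 * n)
  for (k in seq_len(n)) {     # strand 1, pair index k-1
    r <- template_residue(s1[k])
    if (s1[k] == "U" && s2[n - k + 1] == "G") r <- apply_wobble(r, 1L)
    res[[k]] <- place_helical(r, k - 1, strand = 1L, twist = twist,
                              rise = rise)
  }
  for (m in seq_len(n)) {     # strand 2 position m pairs strand-1 n-m+1
    r <- template_residue(s2[m])
    if (s2[m] == "U" && s1[n - m + 1] == "G") r <- apply_wobble(r, 2L)
    res[[n + m]] <- place_helical(r, n - m, strand = 2L, twist = twist,
                                  rise = rise)
  }
  out <- assemble_structure(
    res,
    chains = rep(c("A", "B"), each = n),
    resnos = c(seq_len(n), seq_len(n)),
    resnames = c(s1, s2),
    source_name = paste0("duplex_", seq1))
  attr(out, "dot_bracket") <- paste0(strrep("(", n), "&", strrep(")", n))
  out
}

# Rigid placement of a template residue for single-stranded regions:
# the residue's P lands on `p_target`, its P->O3' span is aligned with the
# unit travel direction `dir`, and the base points along `outward`.
place_chained <- function(res_tbl, p_target, dir, outward) {
  xyz <- as.matrix(res_tbl[, c("x", "y", "z")])
  p0 <- xyz[res_tbl$atom == "P", ]
  o3 <- xyz[res_tbl$atom == "O3'", ]
  cen <- colMeans(xyz[!res_tbl$atom %in% c(rownames(.aform$sugar), "C1'"),
                      , drop = FALSE])
  rot <- frame_rotation(o3 - p0, cen - p0, dir, outward)
  xyz <- sweep(xyz, 2, p0) %*% t(rot)
  xyz <- sweep(xyz, 2, p_target, `+`)
  res_tbl$x <- xyz[, 1]; res_tbl$y <- xyz[, 2]; res_tbl$z <- xyz[, 3]
  res_tbl
}

# Grow a single-stranded arc of residues from anchor `start` (an O3'
# position, may be NULL for a free 5' end) toward `end` (a P position, may
# be NULL for a free 3' end). Returns the placed residue tibbles in chain
# order.
#
# With both anchors, residue travel directions form a constant-turn fan in
# the plane spanned by the chord and `outward` (a planar arc); the start
# angle and per-step turn are solved deterministically so the final O3'
# lands one bond length from `end` (chain closure). With one anchor the
# strand runs straight along `fallback_dir`.
grow_strand <- function(bases, start, end, outward, fallback_dir) {
  nb <- length(bases)
  if (nb == 0) return(list())
  o3p_bond <- 1.607
  tmpl_span <- {
    tmpl <- template_residue("A")
    xyz <- as.matrix(tmpl[, c("x", "y", "z")])
    vec_norm(xyz[tmpl$atom == "O3'", ] - xyz[tmpl$atom == "P", ])
  }
  step_len <- o3p_bond + tmpl_span
  place_along <- function(dirs) {
    res <- vector("list", nb)
    cursor <- start
    for (k in seq_len(nb)) {
      d <- dirs[[k]]
      p_target <- cursor + o3p_bond * d
      res[[k]] <- place_chained(template_residue(bases[k]), p_target, d,
                                outward)
      xyz <- as.matrix(res[[k]][, c("x", "y", "z")])
      cursor <- xyz[res[[k]]$atom == "O3'", ]
    }
    list(res = res, final_o3 = cursor)
  }
  if (!is.null(start) && !is.null(end)) {
    chord <- end - start
    e1 <- vec_unit(chord)
    e2 <- vec_unit(outward - sum(outward * e1) * e1)
    fan <- function(par) {
      phi <- par[1] - (seq_len(nb + 1) - 1) * par[2]
      lapply(phi, function(a) cos(a) * e1 + sin(a) * e2)
    }
    closure <- function(par) {
      dirs <- fan(par)
      endpoint <- start
      for (k in seq_len(nb)) endpoint <- endpoint + step_len * dirs[[k]]
      endpoint <- endpoint + o3p_bond * dirs[[nb + 1]]
      sum((endpoint - end)^2)
    }
    best <- NULL
    for (delta0 in seq(0.2, 1.4, by = 0.4)) {
      o <- optim(c(nb * delta0 / 2, delta0), closure, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 800))
      if (is.null(best) || o$value < best$value) best <- o
      if (best$value < 1e-8) break
    }
    place_along(fan(best$par)[seq_len(nb)])$res
  } else if (!is.null(start)) {
    place_along(rep(list(vec_unit(fallback_dir)), nb))$res
  } else {
    # free 5' tail ending at `end`: build backwards along -fallback_dir
    d <- vec_unit(fallback_dir)
    res <- vector("list", nb)
    cursor <- end   # P of the following residue
    for (k in rev(seq_len(nb))) {
      tmpl <- template_residue(bases[k])
      xyz <- as.matrix(tmpl[, c("x", "y", "z")])
      p0 <- xyz[tmpl$atom == "P", ]
      o3 <- xyz[tmpl$atom == "O3'", ]
      span <- vec_norm(o3 - p0)
      p_target <- cursor - d * (o3p_bond + span)
      res[[k]] <- place_chained(tmpl, p_target, d, outward)
      xyz2 <- as.matrix(res[[k]][, c("x", "y", "z")])
      cursor <- xyz2[res[[k]]$atom == "P", ]
    }
    res
  }
}

#' Build a single-stem fold (hairpin with optional tails) at arbitrary
#' register
#'
#' Positions `stem5_start .. stem5_start + stem_len - 1` pair with
#' `stem3_end .. stem3_end - stem_len + 1` (an A-form stem); the enclosed
#' loop and any 5'/3' tails are grown single-stranded with bases splayed
#' outward. Non-complementary "pairs" are permitted: the residues are placed
#' in pairing geometry regardless of identity, which is how scrambled-2D
#' decoys with the native sequence are produced.
#'
#' @param seq Full-length sequence (string).
#' @param stem5_start 1-based first paired position.
#' @param stem3_end 1-based last paired position (3' side).
#' @param stem_len Number of pairs.
#' @return An [rna_structure] (single chain) with attribute `dot_bracket`
#'   recording the intended pairing pattern.
#' @export
build_stem_loop <- function(seq, stem5_start, stem3_end, stem_len) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  stopifnot(stem_len >= 1, stem5_start >= 1, stem3_end <= n)
  loop_len <- (stem3_end - stem_len) - (stem5_start + stem_len) + 1
  if (loop_len < 3) abort("loop must contain at least 3 nucleotides")

  res <- vector("list", n)
  stem5 <- stem5_start:(stem5_start + stem_len - 1)
  stem3 <- (stem3_end - stem_len + 1):stem3_end
  loop <- (stem5_start + stem_len):(stem3_end - stem_len)
  tail5 <- if (stem5_start > 1) 1:(stem5_start - 1) else integer(0)
  tail3 <- if (stem3_end < n) (stem3_end + 1):n else integer(0)

  for (k in seq_along(stem5)) {
    i <- stem5[k]
    j <- stem3_end - (k - 1)
    r <- template_residue(s[i])
    if (s[i] == "U" && s[j] == "G") r <- apply_wobble(r, 1L)
    res[[i]] <- place_helical(r, k - 1, strand = 1L)
  }
  for (k in seq_along(stem3)) {
    j <- stem3[k]
    i <- stem5_start + (stem3_end - j)      # partner on the 5' side
    pair_idx <- i - stem5_start
    r <- template_residue(s[j])
    if (s[j] == "U" && s[i] == "G") r <- apply_wobble(r, 2L)
    res[[j]] <- place_helical(r, pair_idx, strand = 2L)
  }

  coords_of <- function(i, name) {
    xyz <- as.matrix(res[[i]][, c("x", "y", "z")])
    xyz[res[[i]]$atom == name, ]
  }
  axis_top <- c(0, 0, (stem_len - 1) * .aform$rise)
  axis_bot <- c(0, 0, 0)

  # loop: from strand-1 top O3' to the P of the first 3'-side stem residue
  start <- coords_of(stem5[length(stem5)], "O3'")
  end <- coords_of(stem3[1], "P")
  outward <- vec_unit((start + end) / 2 - axis_top + c(0, 0, 2 * .aform$rise))
  loop_res <- grow_strand(s[loop], start, end, outward, c(0, 0, 1))
  for (k in seq_along(loop)) res[[loop[k]]] <- loop_res[[k]]

  # 5' tail: ends at the P of the first stem residue, runs along -z
  if (length(tail5) > 0) {
    end5 <- coords_of(stem5[1], "P")
    outward5 <- vec_unit(c(end5[1], end5[2], 0))
    tail_res <- grow_strand(s[tail5], NULL, end5, outward5, c(0, 0, 1))
    for (k in seq_along(tail5)) res[[tail5[k]]] <- tail_res[[k]]
  }
  # 3' tail: starts at the O3' of the last stem residue, runs along -z
  if (length(tail3) > 0) {
    start3 <- coords_of(stem3[length(stem3)], "O3'")
    outward3 <- vec_unit(c(start3[1], start3[2], 0))
    tail_res <- grow_strand(s[tail3], start3, NULL, outward3, c(0, 0, -1))
    for (k in seq_along(tail3)) res[[tail3[k]]] <- tail_res[[k]]
  }

  db <- rep(".", n)
  db[stem5] <- "("
  db[stem3] <- ")"
  out <- assemble_structure(
    res, chains = rep("A", n), resnos = seq_len(n), resnames = s,
    source_name = paste0("stem_loop_", seq))
  attr(out, "dot_bracket") <- paste(db, collapse = "")
  out
}

#' Build an ideal hairpin (A-form stem + open loop)
#'
#' The stem is an alternating G-C duplex of `stem_len` pairs unless
#' `stem_seq` is given; the loop bases are splayed outward with no
#' base-base contacts. The construction's dot-bracket is recorded as ground
#' truth in the `dot_bracket` attribute.
#'
#' @param stem_len Number of stem pairs (>= 2).
#' @param loop_seq Loop sequence (>= 3 nucleotides).
#' @param stem_seq Optional 5'-side stem sequence of length `stem_len`.
#' @return An [rna_structure] (single chain).
#' @export
build_hairpin <- function(stem_len, loop_seq, stem_seq = NULL) {
  stopifnot(stem_len >= 2, nchar(loop_seq) >= 3)
  if (is.null(stem_seq)) {
    stem_seq <- paste(rep(c("G", "C"), length.out = stem_len), collapse = "")
  }
  s5 <- strsplit(toupper(stem_seq), "")[[1]]
  stopifnot(length(s5) == stem_len)
  s3 <- reverse_complement(s5)
  seq <- paste0(paste(s5, collapse = ""), toupper(loop_seq),
                paste(s3, collapse = ""))
  n <- nchar(seq)
  out <- build_stem_loop(seq, 1, n, stem_len)
  out$source_name <- paste0("hairpin_", seq)
  out
}

#' Perturb a structure with seeded isotropic Gaussian noise
#'
#' Adds independent N(0, sigma^2) displacements to every heavy-atom
#' coordinate. `sigma = 0` returns identical coordinates. All randomness is
#' confined to the supplied seed (the global RNG state is untouched).
#'
#' @param x An [rna_structure].
#' @param sigma Displacement standard deviation per coordinate, Angstrom.
#' @param seed Integer seed.
#' @return A perturbed [rna_structure].
#' @export
perturb_structure <- function(x, sigma, seed) {
  stopifnot(sigma >= 0)
  out <- x
  if (sigma > 0) {
    n <- nrow(x$atoms)
    noise <- withr::with_seed(seed, matrix(rnorm(3 * n, 0, sigma), n, 3))
    out$atoms$x <- x$atoms$x + noise[, 1]
    out$atoms$y <- x$atoms$y + noise[, 2]
    out$atoms$z <- x$atoms$z + noise[, 3]
  }
  out$source_name <- paste0(x$source_name, "_perturbed", sigma)
  out
}

#' Rebuild a structure with a scrambled secondary structure
#'
#' Detects the native fold, then rebuilds the molecule (same sequence) as a
#' single-stem fold whose register differs from the native pairing pattern,
#' with a pair count within one of the native canonical pair count. Used as
#' a surrogate for decoys generated under non-native 2D constraints.
#'
#' @param x An [rna_structure] with at least one helix.
#' @param seed Integer seed selecting among the admissible registers.
#' @return An [rna_structure] whose `dot_bracket` attribute records the
#'   decoy's intended (non-native) pairing pattern.
#' @export
scramble_2d_decoy <- function(x, seed) {
  n <- n_nucleotides(x)
  s <- gsub("&", "", rna_sequence(x))
  pairs <- detect_base_pairs(x)
  ss <- extract_secondary_structure(pairs, n)
  native_db <- ss$dot_bracket
  p_nat <- sum(!is.na(ss$paired_with)) / 2
  if (p_nat < 1) abort("structure has no helix to scramble")

  cands <- list()
  for (L in max(2, p_nat - 1):(p_nat + 1)) {
    if (n - 2 * L - 2 < 1) next
    for (start in seq_len(n - 2 * L - 2)) {
      for (end in (start + 2 * L + 2):n) {
        loop_len <- (end - L) - (start + L) + 1
        if (loop_len < 3) next
        db <- rep(".", n)
        db[start:(start + L - 1)] <- "("
        db[(end - L + 1):end] <- ")"
        db <- paste(db, collapse = "")
        if (db == native_db) next
        cands[[length(cands) + 1]] <- c(start, end, L)
      }
    }
  }
  if (length(cands) == 0) abort("no admissible scrambled register")
  pick <- withr::with_seed(seed, sample.int(length(cands), 1))
  ch <- cands[[pick]]
  out <- build_stem_loop(s, ch[1], ch[2], ch[3])
  out$source_name <- paste0(x$source_name, "_scrambled", seed)
  out
}

#' Generate a model-consistent synthetic SHAPE profile
#'
#' Runs the prediction pipeline with the supplied ground-truth parameters
#' and multiplies each predicted reactivity by `exp(xi)`,
#' `xi ~ N(0, noise_sigma^2)` (log-normal multiplicative noise, mirroring
#' the error structure of experimental SHAPE data). `noise_sigma = 0`
#' returns the noiseless model prediction.
#'
#' @param x An [rna_structure].
#' @param params Ground-truth model parameters.
#' @param noise_sigma Log-space Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A [shape_profile()].
#' @export
synth_shape <- function(x, params = default_params(), noise_sigma = 0,
                        seed = 1L) {
  stopifnot(noise_sigma >= 0)
  prediction <- predict_profile(x, params = params)
  p <- prediction$features$p
  if (noise_sigma > 0) {
    xi <- withr::with_seed(seed, rnorm(length(p), 0, noise_sigma))
    p <- p * exp(xi)
  }
  shape_profile(position = prediction$features$res_index, reactivity = p)
}
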
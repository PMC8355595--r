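# Per-nucleotide feature assembly and the reactivity model.
#
# The predicted reactivity of nucleotide i is
#     p_i = SF_i * exp(SE_i)
# with the structural factor and energy-like score
#     SF_i = (Abar_SAS(i) + A_SAS0) * F_sug(i) * F_term(i)
#     SE_i = Ebar_2D(i) + Ebar_IE(i) + E_lig(i)
# where barred quantities are neighbor-smoothed profiles of the raw
# interaction energy, 2D pairing energy and 2'-OH accessible surface.

#' Interaction energy per nucleotide
#'
#' Sums, for every nucleotide i, `A * E_bp + B` over all detected base pairs
#' involving i plus the polarity-dependent stacking energy over all stacking
#' partners of i (`e_st_5p` for upstream partners, `e_st_3p` for downstream
#' partners, optionally keyed by the partner's base identity).
#'
#' @param x An [rna_structure].
#' @param pairs Tibble from [detect_base_pairs()].
#' @param stacks Tibble from [detect_stacking()].
#' @param params Model parameters.
#' @return Numeric vector (length = number of nucleotides).
#' @export
interaction_energy <- function(x, pairs, stacks, params) {
  n <- n_nucleotides(x)
  e <- numeric(n)
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      bases <- paste0(pairs$base_i[r], pairs$base_j[r])
      ebp <- lookup_pair_energy(params$e_bp, pairs$pair_type[r], bases,
                                pairs$is_canonical[r])
      contrib <- params$A * ebp + params$B
      e[pairs$i[r]] <- e[pairs$i[r]] + contrib
      e[pairs$j[r]] <- e[pairs$j[r]] + contrib
    }
  }
  if (nrow(stacks) > 0) {
    for (r in seq_len(nrow(stacks))) {
      tab <- if (stacks$polarity[r] == "5p") params$e_st_5p else params$e_st_3p
      e[stacks$i[r]] <- e[stacks$i[r]] +
        lookup_stack_energy(tab, stacks$base_k[r])
    }
  }
  e
}

#' 2D pairing energy per nucleotide
#'
#' `e_2d_pair` at every position paired in the extracted secondary
#' structure, 0 elsewhere. When `include_pseudoknots` is `FALSE`, only
#' tier-1 (nested) pairs count.
#'
#' @param ss An `rna_secondary_structure`.
#' @param params Model parameters.
#' @return Numeric vector of length `ss$length`.
#' @export
pairing_energy_2d <- function(ss, params) {
  paired <- !is.na(ss$paired_with)
  if (!isTRUE(params$include_pseudoknots)) {
    paired <- paired & !is.na(ss$tier) & ss$tier == 1L
  }
  ifelse(paired, params$e_2d_pair, 0)
}

#' Neighbor smoothing of a per-nucleotide profile
#'
#' Weighted average over the asymmetric window `{i-1, i, i+1, i+2}` with
#' weights `weights[1..4]`; at chain ends and chain breaks the window is
#' truncated to in-segment positions and the denominator renormalizes over
#' the retained weights.
#'
#' @param values Numeric vector.
#' @param weights Four nonnegative weights with a positive sum.
#' @param breaks Positions after which a chain break occurs (see
#'   [chain_breaks()]).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, weights, breaks = integer(0)) {
  if (length(weights) != 4 || any(weights < 0) || sum(weights) <= 0) {
    abort("smoothing weights must be 4 nonnegative values with a positive sum")
  }
  n <- length(values)
  out <- numeric(n)
  segments <- break_segments(n, breaks)
  for (seg in segments) {
    lo <- seg[1]; hi <- seg[length(seg)]
    for (i in seg) {
      win <- i + (-1):2
      ok <- win >= lo & win <= hi
      out[i] <- sum(weights[ok] * values[win[ok]]) / sum(weights[ok])
    }
  }
  out
}

#' Terminal factor per nucleotide
#'
#' Accounts for the extra flexibility of the short sequences appended to
#' RNA termini in SHAPE experiments: position i gets `f_term[depth]` where
#' depth is the distance (1-based) from the nearest 5' or 3' end of its
#' chain, and 1 beyond the configured depths.
#'
#' @param chain_lengths Integer vector of chain lengths in file order.
#' @param params Model parameters (`f_term` vector by depth).
#' @return Numeric vector over the concatenated chains.
#' @export
terminal_factor <- function(chain_lengths, params) {
  f <- params$f_term
  unlist(lapply(chain_lengths, function(len) {
    pos <- seq_len(len)
    depth <- pmin(pos, len - pos + 1L)
    ifelse(depth <= length(f), f[depth], 1)
  }), use.names = FALSE)
}

#' Ligand-binding penalty per nucleotide
#'
#' `e_lig` where the user-supplied mask is 1 (nucleotide interacts with a
#' bound ligand), 0 elsewhere. Without a mask all nucleotides are treated as
#' non-interacting.
#'
#' @param mask Numeric/integer 0-1 vector of length N, or `NULL`.
#' @param n Number of nucleotides.
#' @param params Model parameters.
#' @return Numeric vector of length `n`.
#' @export
ligand_penalty <- function(mask, n, params) {
  if (is.null(mask)) return(numeric(n))
  if (length(mask) != n) {
    abort(paste0("mask length ", length(mask),
                 " does not match nucleotide count ", n))
  }
  bad <- which(!mask %in% c(0, 1))
  if (length(bad) > 0) {
    abort(paste0("mask entries must be 0 or 1; offending entry ", bad[1],
                 " = ", mask[bad[1]]))
  }
  ifelse(mask == 1, params$e_lig, 0)
}

#' Predict the SHAPE reactivity profile of a structure
#'
#' Orchestrates the full pipeline: base-pair and stacking annotation, 2D
#' structure extraction, 2'-OH surface area, sugar pucker, terminal and
#' ligand factors, neighbor smoothing, and the final combination
#' `p = SF * exp(SE)`. The returned object carries every intermediate
#' feature for transparency.
#'
#' @param x An [rna_structure].
#' @param params Model parameters; see [default_params()].
#' @param mask Optional 0-1 ligand-interaction mask of length N.
#' @return Object of class `shape_prediction`; see [tidy.shape_prediction()]
#'   for the per-nucleotide feature table.
#' @export
predict_profile <- function(x, params = default_params(), mask = NULL) {
  stopifnot(inherits(x, "rna_structure"))
  params <- validate_params(unclass(params))
  nt <- nucleotides(x)
  n <- nrow(nt)

  pairs <- detect_base_pairs(x, gates = params$pair_gates)
  stacks <- detect_stacking(x, gates = params$stack_gates)
  ss <- extract_secondary_structure(pairs, n)

  e_ie <- interaction_energy(x, pairs, stacks, params)
  e_2d <- pairing_energy_2d(ss, params)

  sasa <- sasa_2oh(x, bead_radius = params$sasa_bead_radius,
                   n_points = params$sasa_n_points)
  a_sas <- sasa$sasa
  sasa_missing <- sasa$missing
  if (any(sasa_missing)) {
    fill <- params$sasa_missing_fill %||% median(a_sas[!sasa_missing])
    if (!is.finite(fill)) fill <- 0
    inform(paste0("imputing missing 2'-OH surface area at ",
                  sum(sasa_missing), " position(s) with ",
                  signif(fill, 4), " A^2"))
    a_sas[sasa_missing] <- fill
  }

  breaks <- chain_breaks(x)
  e_ie_bar <- smooth_profile(e_ie, params$w, breaks)
  e_2d_bar <- smooth_profile(e_2d, params$d, breaks)
  a_sas_bar <- smooth_profile(a_sas, params$a, breaks)

  pucker <- pseudorotation(x)
  f_sug <- sugar_factor(pucker, params)
  chain_lengths <- as.integer(table(factor(nt$chain, levels = unique(nt$chain))))
  f_term <- terminal_factor(chain_lengths, params)
  e_lig <- ligand_penalty(mask, n, params)

  sf <- (a_sas_bar + params$a_sas0) * f_sug * f_term
  se <- e_2d_bar + e_ie_bar + e_lig
  p <- sf * exp(se)

  features <- tibble(
    res_index = nt$res_index, chain = nt$chain, resno = nt$resno,
    base = nt$base,
    e_ie = e_ie, e_2d = e_2d, a_sas = a_sas,
    e_ie_bar = e_ie_bar, e_2d_bar = e_2d_bar, a_sas_bar = a_sas_bar,
    f_sug = f_sug, f_term = f_term, e_lig = e_lig,
    sf = sf, se = se, p = p,
    sasa_missing = sasa_missing,
    pucker_class = pucker$pucker_class)

  structure(
    list(features = features, pairs = pairs, stacks = stacks,
         secondary_structure = ss, params = params,
         source_name = x$source_name, model_id = x$model_id),
    class = "shape_prediction")
}

#' @export
print.shape_prediction <- function(x, ...) {
  cat("<shape_prediction> ", x$source_name, "\n", sep = "")
  cat("  ", nrow(x$features), " nucleotides, ",
      nrow(x$pairs), " base pairs (",
      sum(x$pairs$is_canonical), " canonical), ",
      nrow(x$stacks) / 2, " stacking contacts\n", sep = "")
  cat("  2D: ", x$secondary_structure$dot_bracket, "\n", sep = "")
  cat("  reactivity range: [", signif(min(x$features$p), 4), ", ",
      signif(max(x$features$p), 4), "]\n", sep = "")
  invisible(x)
}

#' Per-nucleotide feature table of a prediction
#'
#' @param x A `shape_prediction`.
#' @param ... Unused.
#' @return Tibble with one row per nucleotide holding the raw and smoothed
#'   features, the factors, and the predicted reactivity `p`.
#' @method tidy shape_prediction
#' @export
tidy.shape_prediction <- function(x, ...) x$features

#' One-row summary of a prediction
#'
#' @param x A `shape_prediction`.
#' @param ... Unused.
#' @return One-row tibble: nucleotide, pair and stack counts, dot-bracket,
#'   and reactivity summary statistics.
#' @method glance shape_prediction
#' @export
glance.shape_prediction <- function(x, ...) {
  tibble(
    n_nt = nrow(x$features),
    n_pairs = nrow(x$pairs),
    n_canonical = sum(x$pairs$is_canonical),
    n_stacks = nrow(x$stacks) / 2,
    dot_bracket = x$secondary_structure$dot_bracket,
    mean_p = mean(x$features$p),
    max_p = max(x$features$p))
}

#' Plot a predicted reactivity profile
#'
#' @param object A `shape_prediction`.
#' @param observed Optional [shape_profile()] of experimental reactivities
#'   to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_prediction
#' @export
autoplot.shape_prediction <- function(object, observed = NULL, ...) {
  df <- object$features |>
    select(position = "res_index", reactivity = "p") |>
    mutate(profile = "predicted")
  if (!is.null(observed)) {
    obs <- as_tibble(observed) |>
      filter(!.data$missing) |>
      select("position", "reactivity") |>
      mutate(profile = "observed")
    df <- bind_rows(df, obs)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$reactivity,
                                   colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "nucleotide position", y = "SHAPE reactivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Convert a prediction to a SHAPE profile
#'
#' @param x A `shape_prediction`.
#' @return A [shape_profile()] of the predicted reactivities.
#' @export
predicted_profile <- function(x) {
  stopifnot(inherits(x, "shape_prediction"))
  shape_profile(position = x$features$res_index, reactivity = x$features$p)
}
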
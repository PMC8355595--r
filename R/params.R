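#' Default model parameters
#'
#' Every tunable symbol of the reactivity model in one list, serializable to
#' and from a YAML config. The shipped defaults are UNTRAINED-DEFAULTS:
#' sign-sensible, order-of-magnitude values chosen for transparent fixtures
#' and tests, not values fitted to experimental SHAPE data (trained values
#' are expected to be supplied through a config file).
#'
#' Components:
#' \describe{
#'   \item{A, B}{Scale and per-pair offset applied to base-pair energies in
#'     the interaction-energy sum.}
#'   \item{e_bp}{Pair-energy table keyed by pair type. Lookup order for a
#'     pair of type `t` and bases `XY`: `"t:XY"`, then `t` (e.g. `"cWW"`),
#'     then `canonical`/`default` by the pair's canonical flag. Energies
#'     are expected to be <= 0 (interactions suppress reactivity).}
#'   \item{e_st_5p, e_st_3p}{Stacking energy for an upstream (5') or
#'     downstream (3') partner; a scalar, or a list keyed by the partner's
#'     base with a `default` entry.}
#'   \item{e_2d_pair}{Energy credited to each partner of a canonical pair in
#'     the extracted 2D structure.}
#'   \item{w, d, a}{Four nonnegative smoothing weights each for the
#'     interaction energy, 2D energy and surface-area profiles (window
#'     positions i-1, i, i+1, i+2).}
#'   \item{a_sas0}{Breathing offset (Angstrom^2) added to the smoothed
#'     surface area; lets an apparently buried 2'-OH retain reactivity.}
#'   \item{f_sug}{Pucker-class -> multiplicative factor map (missing classes
#'     fall back to `other`, then 1).}
#'   \item{f_term}{Terminal factors by depth from either chain end
#'     (`f_term[1]` applies to the first/last nucleotide of each chain).}
#'   \item{e_lig}{Ligand-binding energy penalty applied where the user mask
#'     is 1.}
#'   \item{sasa_missing_fill}{Imputation for missing surface areas; `NULL`
#'     means the per-structure median.}
#'   \item{include_pseudoknots}{Whether pseudoknotted canonical pairs count
#'     in the 2D energy.}
#'   \item{sasa_bead_radius, sasa_n_points}{Probe radius (Angstrom) and
#'     sphere sampling density for the surface-area step.}
#'   \item{pair_gates, stack_gates}{Geometric gates of the annotators.}
#' }
#'
#' @return A list of class `shape_model_params`.
#' @export
default_params <- function() {
  p <- list(
    A = 1, B = 0,
    e_bp = list(canonical = -1, default = -0.5),
    e_st_5p = -0.4,
    e_st_3p = -0.2,
    e_2d_pair = -0.5,
    w = c(1, 2, 1, 1),
    d = c(1, 2, 1, 1),
    a = c(1, 2, 1, 1),
    a_sas0 = 10,
    f_sug = list(`C3'-endo` = 1.0, `C2'-endo` = 1.5, other = 1.0),
    f_term = c(2.0),
    e_lig = -2,
    sasa_missing_fill = NULL,
    include_pseudoknots = TRUE,
    sasa_bead_radius = 2.0,
    sasa_n_points = 960,
    pair_gates = default_pair_gates(),
    stack_gates = default_stack_gates(),
    na_pc_epsilon = 0.01
  )
  validate_params(p)
}

validate_params <- function(p) {
  for (nm in c("w", "d", "a")) {
    wts <- p[[nm]]
    if (length(wts) != 4 || any(wts < 0) || sum(wts) <= 0) {
      abort(paste0("smoothing weights '", nm,
                   "' must be 4 nonnegative values with a positive sum"))
    }
  }
  if (p$a_sas0 < 0) abort("a_sas0 must be >= 0")
  if (any(unlist(p$f_sug) <= 0)) abort("f_sug factors must be > 0")
  if (any(p$f_term <= 0)) abort("f_term factors must be > 0")
  energies <- c(unlist(p$e_bp), unlist(p$e_st_5p), unlist(p$e_st_3p),
                p$e_2d_pair, p$e_lig)
  if (any(energies > 0)) {
    warn("positive interaction energies supplied; interactions usually suppress reactivity (energies <= 0)")
  }
  structure(p, class = "shape_model_params")
}

#' Read model parameters from a YAML config file
#'
#' Keys absent from the file keep their defaults, so a config may override
#' any subset of [default_params()].
#'
#' @param path YAML file path.
#' @return A `shape_model_params` list.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  p <- unclass(default_params())
  for (nm in names(user)) {
    val <- user[[nm]]
    if (nm %in% c("w", "d", "a", "f_term")) val <- as.numeric(val)
    if (nm %in% c("pair_gates", "stack_gates")) {
      p[[nm]] <- utils::modifyList(p[[nm]], val)
      next
    }
    p[nm] <- list(val)   # preserves explicit nulls (e.g. sasa_missing_fill)
  }
  validate_params(p)
}

#' Write model parameters to a YAML config file
#'
#' Round-trips losslessly through [read_params()].
#'
#' @param params A `shape_model_params` list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# Energy lookup helpers -------------------------------------------------

lookup_pair_energy <- function(e_bp, pair_type, bases, canonical) {
  key_full <- paste0(pair_type, ":", bases)
  if (!is.null(e_bp[[key_full]])) return(e_bp[[key_full]])
  if (!is.null(e_bp[[pair_type]])) return(e_bp[[pair_type]])
  if (canonical && !is.null(e_bp[["canonical"]])) return(e_bp[["canonical"]])
  if (!is.null(e_bp[["default"]])) return(e_bp[["default"]])
  warn(paste0("no energy for pair type '", pair_type,
              "' and no default; using 0"))
  0
}

lookup_stack_energy <- function(e_st, partner_base) {
  if (is.numeric(e_st) && length(e_st) == 1 && is.null(names(e_st))) {
    return(e_st)
  }
  tab <- as.list(e_st)
  if (!is.null(tab[[partner_base]])) return(tab[[partner_base]])
  if (!is.null(tab[["default"]])) return(tab[["default"]])
  0
}
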
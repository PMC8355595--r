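#' RNA structure objects
#'
#' An `rna_structure` wraps a tibble of heavy atoms belonging to a cleaned
#' RNA molecule (one conformation). Rows are atoms; columns identify the
#' chain, author residue number, residue name, the 1-based nucleotide index
#' along the cleaned concatenated chains (`res_index`), the atom name,
#' element, Cartesian coordinates in Angstrom, and whether the residue is a
#' modified nucleotide (kept as backbone only).
#'
#' @param atoms Atom tibble with columns `chain`, `resno`, `resname`,
#'   `res_index`, `atom`, `element`, `x`, `y`, `z`, `is_modified`.
#' @param model_id Integer model number for multi-model files.
#' @param source_name Provenance label (file name, fixture name, ...).
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(atoms, model_id = 1L, source_name = "structure") {
  required <- c("chain", "resno", "resname", "res_index", "atom",
                "element", "x", "y", "z", "is_modified")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("empty structure: no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  dup <- atoms |>
    dplyr::count(.data$res_index, .data$atom) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate atom name within residue at position ",
                 dup$res_index[1], " (", dup$atom[1], ")"))
  }
  structure(
    list(atoms = as_tibble(atoms), model_id = as.integer(model_id),
         source_name = source_name),
    class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  nt <- nucleotides(x)
  cat("<rna_structure> ", x$source_name,
      if (!is.na(x$model_id)) paste0(" (model ", x$model_id, ")"), "\n", sep = "")
  cat("  ", nrow(nt), " nucleotides, ", nrow(x$atoms), " heavy atoms, ",
      dplyr::n_distinct(nt$chain), " chain(s)\n", sep = "")
  cat("  sequence: ", rna_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Per-nucleotide summary of a structure
#'
#' @param x An `rna_structure`.
#' @return Tibble with one row per nucleotide: `res_index`, `chain`, `resno`,
#'   `resname`, `base` (parent base letter), `n_atoms`, `is_modified`.
#' @export
nucleotides <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  ri <- x$atoms$res_index
  ord <- order(ri)
  first_idx <- ord[!duplicated(ri[ord])]
  counts <- tabulate(ri)
  resname <- x$atoms$resname[first_idx]
  tibble(
    res_index = ri[first_idx],
    chain = x$atoms$chain[first_idx],
    resno = x$atoms$resno[first_idx],
    resname = resname,
    base = parent_base(resname),
    n_atoms = counts[counts > 0],
    is_modified = x$atoms$is_modified[first_idx])
}

n_nucleotides <- function(x) dplyr::n_distinct(x$atoms$res_index)

#' One-letter sequence of a cleaned structure
#'
#' Chains are reported 5' to 3' in file order and joined with `&`. Modified
#' residues are mapped to their parent base where known, otherwise `N`.
#'
#' @param x An `rna_structure`.
#' @return A single string such as `"GGGG&CCCC"`.
#' @export
rna_sequence <- function(x) {
  nt <- nucleotides(x)
  per_chain <- nt |>
    group_by(.data$chain) |>
    summarise(seq = paste(.data$base, collapse = ""), .groups = "drop")
  # preserve file order of chains
  ord <- unique(nt$chain)
  paste(per_chain$seq[match(ord, per_chain$chain)], collapse = "&")
}

# Matrix of coordinates for selected rows of the atom table.
atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# Named coordinate lookup for a single residue; NULL when absent.
residue_atom <- function(atoms, idx, name) {
  k <- which(atoms$res_index == idx & atoms$atom == name)
  if (length(k) == 0) return(NULL)
  k <- k[1]
  c(atoms$x[k], atoms$y[k], atoms$z[k])
}

#' Chain and break segmentation
#'
#' Neighbor smoothing never crosses a chain boundary or a chain break. A
#' break is declared between consecutive nucleotides of one chain when the
#' author residue numbering jumps or when the O3'(i)-P(i+1) distance exceeds
#' `max_o3p_dist` (physically disconnected backbone).
#'
#' @param x An `rna_structure`.
#' @param max_o3p_dist Bonding cutoff in Angstrom for O3'-P continuity.
#' @return Integer vector of positions `i` such that a break lies between
#'   nucleotide `i` and `i + 1` (chain boundaries included).
#' @export
chain_breaks <- function(x, max_o3p_dist = 2.5) {
  nt <- nucleotides(x)
  n <- nrow(nt)
  if (n < 2) return(integer(0))
  breaks <- integer(0)
  for (i in seq_len(n - 1)) {
    if (nt$chain[i] != nt$chain[i + 1]) {
      breaks <- c(breaks, i)
      next
    }
    if (nt$resno[i + 1] - nt$resno[i] != 1L) {
      breaks <- c(breaks, i)
      next
    }
    o3 <- residue_atom(x$atoms, nt$res_index[i], "O3'")
    p <- residue_atom(x$atoms, nt$res_index[i + 1], "P")
    if (!is.null(o3) && !is.null(p) && vec_norm(o3 - p) > max_o3p_dist) {
      breaks <- c(breaks, i)
    }
  }
  breaks
}

# Split 1..n into runs delimited by `breaks` (positions after which to cut).
break_segments <- function(n, breaks) {
  cuts <- sort(unique(c(0L, as.integer(breaks), n)))
  lapply(seq_len(length(cuts) - 1), function(k) (cuts[k] + 1L):cuts[k + 1L])
}

# Parent base for standard and known modified residue names; NA -> "N".
parent_base <- function(resname) {
  map <- modified_residue_table()
  std <- c(A = "A", U = "U", G = "G", C = "C",
           RA = "A", RU = "U", RG = "G", RC = "C")
  out <- unname(std[resname])
  idx <- is.na(out)
  out[idx] <- unname(map[resname[idx]])
  out[is.na(out)] <- "N"
  out
}

# Known modified ribonucleotides and their parent bases. Configurable at the
# read step through `extra_modified`.
modified_residue_table <- function() {
  c(PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", OMU = "U", UR3 = "U",
    "1MA" = "A", MA6 = "A", OMA = "A", A2M = "A",
    "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", YG = "G",
    "5MC" = "C", OMC = "C", CCC = "C")
}

backbone_atom_names <- function() {
  c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
    "C3'", "O3'", "C2'", "O2'", "C1'")
}
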
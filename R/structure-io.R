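#' Read and clean an RNA structure from a PDB file
#'
#' Parses a PDB file (via [bio3d::read.pdb()]) and applies the input
#' validation rules of the prediction pipeline: everything that is not an
#' RNA residue (waters, ions, proteins, DNA, free ligands) is removed; for
#' atoms with alternate locations only the first occurrence is kept;
#' modified nucleotides are stripped to their backbone atoms; hydrogens are
#' dropped; residues lacking both C1' and C4' are discarded with a warning.
#'
#' A residue counts as RNA when its name is one of A/U/G/C (or RA/RU/RG/RC)
#' or a known modified ribonucleotide, and it contains an O2' or C1' atom.
#' DNA residues (no O2', DA/DT/DG/DC/T names) are removed.
#'
#' @param path Path to a PDB file (single- or multi-model).
#' @param model 1-based model index for multi-model files (default first).
#' @param extra_modified Optional named character vector extending the
#'   built-in modified-residue table (names = residue codes, values = parent
#'   bases).
#' @return An [rna_structure].
#' @export
read_rna_pdb <- function(path, model = 1L, extra_modified = NULL) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                   verbose = FALSE)),
    error = function(e) {
      abort(paste0("cannot parse PDB file '", path, "': ",
                   conditionMessage(e)))
    })
  n_models <- nrow(pdb$xyz)
  if (model < 1 || model > n_models) {
    abort(paste0("model ", model, " not present in '", path, "' (",
                 n_models, " model(s))"))
  }
  atoms <- pdb_model_atoms(pdb, model)
  cleaned <- clean_rna_atoms(atoms, extra_modified = extra_modified,
                             source = basename(path))
  rna_structure(cleaned, model_id = model, source_name = basename(path))
}

#' Read PDB text (character vector of lines) as an RNA structure
#'
#' Convenience wrapper around [read_rna_pdb()] for in-memory PDB records.
#'
#' @param lines Character vector of PDB lines.
#' @inheritParams read_rna_pdb
#' @return An [rna_structure].
#' @export
read_rna_pdb_text <- function(lines, model = 1L, extra_modified = NULL) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  out <- read_rna_pdb(tf, model = model, extra_modified = extra_modified)
  out$source_name <- "pdb_text"
  out
}

# Extract a per-model atom tibble (file order preserved) from a bio3d pdb.
pdb_model_atoms <- function(pdb, model) {
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  tibble(
    line = seq_len(nrow(at)),
    record = at$type,
    atom = normalize_atom_name(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = infer_element(at$elesy, at$elety)
  )
}

normalize_atom_name <- function(name) {
  gsub("\\*", "'", trimws(name))
}

infer_element <- function(elesy, elety) {
  el <- trimws(ifelse(is.na(elesy), "", elesy))
  need <- el == ""
  if (any(need)) {
    # strip digits and primes, first alphabetic character wins
    guess <- toupper(substr(gsub("[^A-Za-z]", "", trimws(elety[need])), 1, 1))
    el[need] <- guess
  }
  toupper(el)
}

# Core cleanup shared by all readers. Input: raw atom tibble in file order.
clean_rna_atoms <- function(atoms, extra_modified = NULL, source = "input") {
  mod_table <- c(modified_residue_table(), extra_modified)
  std <- c("A", "U", "G", "C", "RA", "RU", "RG", "RC")

  atoms <- atoms |> filter(!.data$element %in% c("H", "D"))

  atoms <- atoms |>
    mutate(res_key = paste(.data$chain, .data$resno, .data$insert, sep = "|"))
  res_order <- unique(atoms$res_key)

  keep_res <- atoms |>
    group_by(.data$res_key) |>
    summarise(
      resname = first(.data$resname),
      has_ribose = any(.data$atom %in% c("O2'", "C1'")),
      has_anchor = any(.data$atom %in% c("C1'", "C4'")),
      .groups = "drop") |>
    mutate(
      is_std = .data$resname %in% std,
      is_mod = .data$resname %in% names(mod_table),
      is_rna = (.data$is_std | .data$is_mod) & .data$has_ribose)

  dropped_anchor <- keep_res |> filter(.data$is_rna & !.data$has_anchor)
  if (nrow(dropped_anchor) > 0) {
    warn(paste0("discarding ", nrow(dropped_anchor),
                " residue(s) lacking both C1' and C4' in ", source))
  }
  keep_keys <- keep_res$res_key[keep_res$is_rna & keep_res$has_anchor]
  atoms <- atoms |> filter(.data$res_key %in% keep_keys)
  if (nrow(atoms) == 0) {
    abort(paste0("no RNA residues remain after cleaning '", source, "'"))
  }

  # altloc: first occurrence (file order) of each atom name within a residue
  atoms <- atoms |>
    group_by(.data$res_key, .data$atom) |>
    dplyr::slice_min(.data$line, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$line)

  # modified residues: backbone only
  atoms <- atoms |>
    mutate(is_modified = !.data$resname %in% std) |>
    filter(!.data$is_modified | .data$atom %in% backbone_atom_names())

  keep_keys <- intersect(res_order, unique(atoms$res_key))
  atoms <- atoms |>
    mutate(res_index = match(.data$res_key, keep_keys)) |>
    arrange(.data$line)

  atoms |>
    select("chain", "resno", "resname", "res_index", "atom",
           "element", "x", "y", "z", "is_modified")
}

#' Read a conformational ensemble
#'
#' Accepts either a character vector of PDB paths (one conformation each;
#' multi-model files contribute all their models) or a single multi-model
#' PDB. All cleaned members must share the same sequence; offenders are
#' reported by name and the call errors.
#'
#' @param paths Character vector of PDB file paths.
#' @inheritParams read_rna_pdb
#' @return List of [rna_structure] objects in input order, named by source
#'   (and model for multi-model files).
#' @export
read_rna_ensemble <- function(paths, extra_modified = NULL) {
  members <- list()
  failures <- character(0)
  for (path in paths) {
    n_models <- tryCatch({
      pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                              verbose = FALSE))
      nrow(pdb$xyz)
    }, error = function(e) {
      failures <<- c(failures, paste0(path, ": ", conditionMessage(e)))
      0L
    })
    if (n_models == 0) next
    for (m in seq_len(n_models)) {
      s <- tryCatch(read_rna_pdb(path, model = m,
                                 extra_modified = extra_modified),
                    error = function(e) {
                      failures <<- c(failures,
                                     paste0(path, " model ", m, ": ",
                                            conditionMessage(e)))
                      NULL
                    })
      if (is.null(s)) next
      nm <- if (n_models > 1) {
        paste0(basename(path), "#", m)
      } else {
        basename(path)
      }
      members[[nm]] <- s
    }
  }
  if (length(failures) > 0) {
    warn(paste0("skipped ensemble member(s):\n  ",
                paste(failures, collapse = "\n  ")))
  }
  if (length(members) == 0) abort("empty ensemble: no readable members")
  seqs <- map_chr(members, rna_sequence)
  ref <- seqs[[1]]
  bad <- names(seqs)[seqs != ref]
  if (length(bad) > 0) {
    abort(paste0("ensemble members differ in sequence from '",
                 names(seqs)[1], "': ", paste(bad, collapse = ", ")))
  }
  members
}

#' Write a structure (or list of structures) to a PDB file
#'
#' Structures in a list are emitted as consecutive MODEL/ENDMDL blocks.
#' Coordinates are written at standard PDB precision (3 decimals).
#'
#' @param x An [rna_structure] or a list of them (shared sequence assumed).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rna_pdb <- function(x, path) {
  members <- if (inherits(x, "rna_structure")) list(x) else x
  lines <- character(0)
  multi <- length(members) > 1
  for (m in seq_along(members)) {
    s <- members[[m]]
    stopifnot(inherits(s, "rna_structure"))
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    prev_chain <- NULL
    for (i in seq_len(nrow(s$atoms))) {
      a <- s$atoms[i, ]
      if (!is.null(prev_chain) && a$chain != prev_chain) {
        lines <- c(lines, "TER")
      }
      prev_chain <- a$chain
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(serial, a))
    }
    lines <- c(lines, "TER", if (multi) "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

format_pdb_atom <- function(serial, a) {
  name <- a$atom
  # names up to 3 characters start in column 14
  name_field <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else name
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_field, a$resname, a$chain, a$resno,
          a$x, a$y, a$z, 1.00, 0.00, a$element)
}
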
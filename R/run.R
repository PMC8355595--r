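# High-level runs tying the pipeline together: predict, sieve, annotate,
# fixtures. These back the command-line interface; each writes a manifest
# (config echo + package version + input checksums) and tab-separated
# outputs whose first lines are comment headers naming the tool version and
# config checksum, so identical inputs give byte-identical outputs.

pkg_version <- function() {
  as.character(utils::packageVersion("shapesieve"))
}

config_checksum <- function(params) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  write_params(params, tf)
  unname(tools::md5sum(tf))
}

output_header <- function(params) {
  paste0("# shapesieve v", pkg_version(), " config=", config_checksum(params))
}

write_tsv_report <- function(df, path, params, extra_header = NULL) {
  lines <- c(output_header(params), extra_header,
             paste(names(df), collapse = "\t"))
  if (nrow(df) > 0) {
    body <- apply(df, 1, function(row) paste(trimws(row), collapse = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

write_manifest <- function(out_dir, params, inputs, seed) {
  manifest <- list(
    tool = "shapesieve",
    version = pkg_version(),
    seed = seed,
    config_checksum = config_checksum(params),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    params = unclass(params))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

resolve_params <- function(params) {
  if (is.null(params)) return(default_params())
  if (is.character(params)) return(read_params(params))
  validate_params(unclass(params))
}

#' Run the prediction pipeline on one structure
#'
#' Writes `prediction.tsv` (full per-nucleotide feature table),
#' `prediction.shape` (two-column SHAPE dialect), `dotbracket.txt`, a
#' `manifest.yaml`, and — when an experimental profile is supplied — a
#' `correlation.txt` with the regular and noise-adjusted Pearson
#' correlations.
#'
#' @param pdb Path to the input PDB file.
#' @param out_dir Output directory (created if absent).
#' @param shape Optional experimental SHAPE profile path.
#' @param mask Optional MASK file path.
#' @param params Model parameters: a `shape_model_params`, a YAML config
#'   path, or `NULL` for defaults.
#' @param model Model index for multi-model PDB files.
#' @param offset Position offset applied to the experimental profile.
#' @param seed Seed recorded in the manifest (the prediction itself is
#'   deterministic).
#' @return Invisibly, a list with the `shape_prediction` and (if computed)
#'   the correlations.
#' @export
run_predict <- function(pdb, out_dir, shape = NULL, mask = NULL,
                        params = NULL, model = 1L, offset = 0L, seed = 1L) {
  params <- resolve_params(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- read_rna_pdb(pdb, model = model)
  mask_vec <- if (!is.null(mask)) read_mask(mask, n_nucleotides(x)) else NULL
  prediction <- predict_profile(x, params = params, mask = mask_vec)

  feats <- tidy(prediction) |>
    mutate(across(dplyr::where(is.numeric), ~ formatC(.x, digits = 6,
                                                      format = "g")))
  write_tsv_report(feats, file.path(out_dir, "prediction.tsv"), params)
  write_shape(predicted_profile(prediction),
              file.path(out_dir, "prediction.shape"),
              header = sub("^# ", "", output_header(params)))
  writeLines(c(output_header(params),
               prediction$secondary_structure$dot_bracket),
             file.path(out_dir, "dotbracket.txt"))

  cors <- NULL
  if (!is.null(shape)) {
    obs <- read_shape(shape, offset = offset)
    cors <- list(
      pc = pearson_cor(predicted_profile(prediction), obs),
      na_pc = noise_adjusted_pearson(predicted_profile(prediction), obs,
                                     epsilon = params$na_pc_epsilon %||% 0.01))
    writeLines(c(output_header(params),
                 sprintf("PC\t%.6f", cors$pc),
                 sprintf("naPC\t%.6f", cors$na_pc)),
               file.path(out_dir, "correlation.txt"))
  }
  write_manifest(out_dir, params,
                 inputs = c(pdb, shape, mask), seed = seed)
  invisible(list(prediction = prediction, correlations = cors))
}

#' Sieve an ensemble and write the ranked report
#'
#' Accepts a directory of PDB files, a vector of paths, or one multi-model
#' PDB. Writes `sieve.tsv` sorted by noise-adjusted correlation plus a
#' manifest; per-member failures are logged and skipped.
#'
#' @param input Ensemble source (directory, file paths, or multi-model PDB).
#' @param shape Experimental SHAPE profile path (required).
#' @param out_dir Output directory.
#' @param reference Optional reference PDB for the RMSD column.
#' @param mask,params,offset,seed As in [run_predict()].
#' @return Invisibly, the `shape_sieve` tibble.
#' @export
run_sieve <- function(input, shape, out_dir, reference = NULL, mask = NULL,
                      params = NULL, offset = 0L, seed = 1L) {
  params <- resolve_params(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- if (length(input) == 1 && dir.exists(input)) {
    sort(list.files(input, pattern = "\\.pdb$", ignore.case = TRUE,
                    full.names = TRUE))
  } else {
    input
  }
  if (length(paths) == 0) abort("empty ensemble: no PDB files found")
  ensemble <- read_rna_ensemble(paths)
  obs <- read_shape(shape, offset = offset)
  ref <- if (!is.null(reference)) read_rna_pdb(reference) else NULL
  mask_vec <- if (!is.null(mask)) {
    read_mask(mask, n_nucleotides(ensemble[[1]]))
  } else {
    NULL
  }
  report <- sieve(ensemble, obs, params = params, reference = ref,
                  mask = mask_vec)
  out <- as_tibble(report) |>
    mutate(across(c("pc", "na_pc"), ~ sprintf("%.6f", .x)),
           rmsd = ifelse(is.na(.data$rmsd), "NA", sprintf("%.4f", .data$rmsd)))
  write_tsv_report(out, file.path(out_dir, "sieve.tsv"), params)
  write_manifest(out_dir, params,
                 inputs = c(paths, shape, reference, mask), seed = seed)
  invisible(report)
}

#' Write annotation tables for one structure
#'
#' Emits `pairs.tsv`, `stacks.tsv`, `dotbracket.txt` and `geometry.tsv`
#' (surface area, pseudorotation, pucker class per nucleotide).
#'
#' @inheritParams run_predict
#' @return Invisibly, a list of the annotation tables.
#' @export
run_annotate <- function(pdb, out_dir, params = NULL, model = 1L,
                         seed = 1L) {
  params <- resolve_params(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- read_rna_pdb(pdb, model = model)
  pairs <- detect_base_pairs(x, gates = params$pair_gates)
  stacks <- detect_stacking(x, gates = params$stack_gates)
  ss <- extract_secondary_structure(pairs, n_nucleotides(x))
  sasa <- sasa_2oh(x, bead_radius = params$sasa_bead_radius,
                   n_points = params$sasa_n_points)
  pucker <- pseudorotation(x)
  geometry <- sasa |>
    left_join(pucker, by = "res_index", suffix = c("_sasa", "_pucker")) |>
    mutate(across(dplyr::where(is.numeric), ~ formatC(.x, digits = 6,
                                                      format = "g")))
  write_tsv_report(pairs |> mutate(across(dplyr::where(is.numeric),
                                          ~ formatC(.x, digits = 6,
                                                    format = "g"))),
                   file.path(out_dir, "pairs.tsv"), params)
  write_tsv_report(stacks |> mutate(across(dplyr::where(is.numeric),
                                           ~ formatC(.x, digits = 6,
                                                     format = "g"))),
                   file.path(out_dir, "stacks.tsv"), params)
  writeLines(c(output_header(params), ss$dot_bracket),
             file.path(out_dir, "dotbracket.txt"))
  write_tsv_report(geometry, file.path(out_dir, "geometry.tsv"), params)
  write_manifest(out_dir, params, inputs = pdb, seed = seed)
  invisible(list(pairs = pairs, stacks = stacks, secondary_structure = ss,
                 geometry = geometry))
}

#' Emit regenerable fixture files
#'
#' Writes a PDB, the construction dot-bracket, and a synthetic SHAPE profile
#' for a named fixture so test assets can be regenerated from the command
#' line.
#'
#' @param kind `"duplex"` or `"hairpin"`.
#' @param out_dir Output directory.
#' @param seq1 Duplex strand-1 sequence (duplex only).
#' @param stem_len,loop_seq Hairpin geometry (hairpin only).
#' @param noise_sigma Log-normal noise level of the emitted SHAPE profile.
#' @param seed Seed for the profile noise.
#' @param params Model parameters for the profile generation.
#' @return Invisibly, the generated [rna_structure].
#' @export
run_fixtures <- function(kind = c("hairpin", "duplex"), out_dir,
                         seq1 = "GGGC", stem_len = 4, loop_seq = "GAAA",
                         noise_sigma = 0, seed = 1L, params = NULL) {
  kind <- match.arg(kind)
  params <- resolve_params(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- if (kind == "duplex") {
    build_duplex(seq1)
  } else {
    build_hairpin(stem_len, loop_seq)
  }
  write_rna_pdb(x, file.path(out_dir, paste0(kind, ".pdb")))
  writeLines(c(output_header(params), attr(x, "dot_bracket")),
             file.path(out_dir, paste0(kind, ".dotbracket")))
  profile <- synth_shape(x, params = params, noise_sigma = noise_sigma,
                         seed = seed)
  write_shape(profile, file.path(out_dir, paste0(kind, ".shape")),
              header = sub("^# ", "", output_header(params)))
  write_manifest(out_dir, params, inputs = character(0), seed = seed)
  invisible(x)
}
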
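# SHAPE profiles, profile correlations, RMSD, and ensemble sieving.

#' SHAPE profile objects
#'
#' A per-nucleotide reactivity vector with missing-data markers. The common
#' two-column text dialect uses `-999` (any value at or below `-500` is
#' treated the same way) for positions without data.
#'
#' @param position 1-based integer positions (strictly increasing).
#' @param reactivity Numeric reactivities; values <= -500 mark missing data.
#' @param missing Optional logical vector overriding the sentinel rule.
#' @return A tibble of class `shape_profile` with columns `position`,
#'   `reactivity`, `missing`.
#' @export
shape_profile <- function(position, reactivity, missing = NULL) {
  position <- as.integer(position)
  if (length(position) != length(reactivity)) {
    abort("position and reactivity lengths differ")
  }
  if (length(position) == 0) abort("empty SHAPE profile")
  if (any(duplicated(position))) {
    abort(paste0("duplicate profile position: ",
                 position[duplicated(position)][1]))
  }
  if (is.unsorted(position, strictly = TRUE)) {
    ord <- order(position)
    position <- position[ord]
    reactivity <- reactivity[ord]
    if (!is.null(missing)) missing <- missing[ord]
  }
  if (is.null(missing)) missing <- reactivity <= -500
  out <- tibble(position = position, reactivity = as.numeric(reactivity),
                missing = missing)
  class(out) <- c("shape_profile", class(out))
  out
}

#' Read a SHAPE profile file
#'
#' Whitespace-delimited lines `index reactivity`; `#` comments and blank
#' lines are ignored; `-999` (or any value <= -500) marks missing data.
#'
#' @param path File path.
#' @param offset Integer added to the file's position column, to reconcile
#'   experimental numbering with the cleaned structure's 1-based positions.
#' @return A [shape_profile()].
#' @export
read_shape <- function(path, offset = 0L) {
  if (!file.exists(path)) abort(paste0("SHAPE file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) abort(paste0("empty SHAPE profile: ", path))
  pos <- numeric(length(keep))
  val <- numeric(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 2) {
      abort(paste0(path, " line ", ln, ": expected 'index reactivity'"))
    }
    suppressWarnings({
      pos[k] <- as.numeric(fields[1])
      val[k] <- as.numeric(fields[2])
    })
    if (is.na(pos[k]) || is.na(val[k])) {
      abort(paste0(path, " line ", ln, ": non-numeric field"))
    }
  }
  if (any(duplicated(pos))) {
    abort(paste0(path, ": duplicate index ", pos[duplicated(pos)][1]))
  }
  shape_profile(position = pos + offset, reactivity = val)
}

#' Write a SHAPE profile file
#'
#' @param profile A [shape_profile()].
#' @param path Output path.
#' @param header Optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_shape <- function(profile, path, header = NULL) {
  vals <- ifelse(profile$missing, -999, profile$reactivity)
  lines <- c(
    if (!is.null(header)) paste0("# ", header),
    sprintf("%d\t%.6f", profile$position, vals))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-interaction MASK file
#'
#' Either two columns `index 0|1` or a single 0/1 column (positions implied
#' 1..N).
#'
#' @param path File path.
#' @param n Expected nucleotide count (checked when two-column).
#' @return Integer 0-1 vector of length `n`.
#' @export
read_mask <- function(path, n) {
  if (!file.exists(path)) abort(paste0("MASK file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  mask <- rep(0L, n)
  if (length(keep) == 0) return(mask)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  ncol1 <- length(fields[[1]])
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- fields[[k]]
    if (ncol1 == 1) {
      v <- suppressWarnings(as.numeric(f[1]))
      if (is.na(v) || !v %in% c(0, 1)) {
        abort(paste0(path, " line ", ln, ": mask entries must be 0 or 1"))
      }
      if (k > n) abort(paste0(path, ": more mask entries than nucleotides"))
      mask[k] <- as.integer(v)
    } else {
      idx <- suppressWarnings(as.integer(f[1]))
      v <- suppressWarnings(as.numeric(f[2]))
      if (is.na(idx) || is.na(v)) {
        abort(paste0(path, " line ", ln, ": non-numeric field"))
      }
      if (!v %in% c(0, 1)) {
        abort(paste0(path, " line ", ln, ": mask entries must be 0 or 1"))
      }
      if (idx < 1 || idx > n) {
        abort(paste0(path, " line ", ln, ": index ", idx,
                     " outside 1..", n))
      }
      mask[idx] <- as.integer(v)
    }
  }
  mask
}

# Align two profiles on jointly non-missing positions.
joint_positions <- function(pred, obs) {
  pred <- as_profile(pred)
  obs <- as_profile(obs)
  merged <- dplyr::inner_join(
    pred |> filter(!.data$missing) |>
      select("position", pred = "reactivity"),
    obs |> filter(!.data$missing) |>
      select("position", obs = "reactivity"),
    by = "position")
  if (nrow(merged) < 3) {
    abort("fewer than 3 jointly non-missing positions; correlation undefined")
  }
  merged
}

as_profile <- function(x) {
  if (inherits(x, "shape_profile")) return(x)
  if (inherits(x, "shape_prediction")) return(predicted_profile(x))
  if (is.numeric(x)) {
    return(shape_profile(position = seq_along(x), reactivity = x))
  }
  abort("expected a shape_profile, shape_prediction, or numeric vector")
}

#' Pearson correlation between two SHAPE profiles
#'
#' Standard product-moment correlation over jointly non-missing positions.
#'
#' @param pred,obs [shape_profile()]s (or numeric vectors / predictions).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(pred, obs) {
  m <- joint_positions(pred, obs)
  if (sd(m$pred) == 0 || sd(m$obs) == 0) {
    abort("zero variance in profile; correlation undefined")
  }
  cor(m$pred, m$obs)
}

#' Noise-adjusted Pearson correlation
#'
#' Respects the log-normality of SHAPE reactivities and their noise: both
#' profiles are log-transformed (`x -> log(x + epsilon)` after clamping
#' small negative experimental values in `(-500, 0)` to zero), and each
#' position is reweighted by `1 / (1 + (noise_i / sigma_obs)^2)` inside a
#' weighted product-moment correlation, where `sigma_obs` is the standard
#' deviation of the log-transformed observed profile. With zero noise this
#' reduces to the plain correlation of the log-profiles; a position with
#' infinite noise drops out entirely.
#'
#' @param pred,obs [shape_profile()]s (or numeric vectors / predictions).
#' @param noise Scalar noise floor or per-position noise standard-deviation
#'   estimates aligned with `obs` positions (recycled when scalar).
#' @param epsilon Log-transform floor (default 0.01).
#' @return Weighted correlation coefficient in `[-1, 1]`.
#' @export
noise_adjusted_pearson <- function(pred, obs, noise = 0, epsilon = 0.01) {
  obs <- as_profile(obs)
  if (any(noise < 0, na.rm = TRUE)) abort("noise must be >= 0")
  if (length(noise) == 1) {
    noise <- rep(noise, nrow(obs))
  } else if (length(noise) != nrow(obs)) {
    abort("per-position noise must match the observed profile length")
  }
  noise_tbl <- tibble(position = obs$position, noise = as.numeric(noise))
  m <- joint_positions(pred, obs) |>
    left_join(noise_tbl, by = "position")
  clamp <- function(v) ifelse(v < 0, 0, v)
  lp <- log(clamp(m$pred) + epsilon)
  lo <- log(clamp(m$obs) + epsilon)
  sigma_obs <- sd(lo)
  if (sigma_obs == 0 || sd(lp) == 0) {
    abort("zero variance in log-profile; correlation undefined")
  }
  w <- 1 / (1 + (m$noise / sigma_obs)^2)
  w[is.infinite(m$noise)] <- 0
  if (sum(w > 0) < 3) {
    abort("fewer than 3 positions with positive weight")
  }
  weighted_pearson(lp, lo, w)
}

weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxx <- sum(w * (x - mx)^2)
  cyy <- sum(w * (y - my)^2)
  if (cxx == 0 || cyy == 0) abort("zero weighted variance; correlation undefined")
  cxy / sqrt(cxx * cyy)
}

#' Heavy-atom RMSD after optimal superposition
#'
#' Atoms are matched by nucleotide index and atom name over the shared heavy
#' atoms of the two structures (same sequence assumed); the RMSD is computed
#' after optimal least-squares rigid superposition (Kabsch algorithm with
#' reflection guard).
#'
#' @param a,b [rna_structure]s of the same molecule.
#' @return RMSD in Angstrom.
#' @export
rmsd_heavy <- function(a, b) {
  key_a <- paste(a$atoms$res_index, a$atoms$atom)
  key_b <- paste(b$atoms$res_index, b$atoms$atom)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 3) abort("fewer than 3 shared heavy atoms")
  ma <- atom_xyz(a$atoms)[match(shared, key_a), , drop = FALSE]
  mb <- atom_xyz(b$atoms)[match(shared, key_b), , drop = FALSE]
  fit <- kabsch_fit(mb, ma)
  mb_fit <- apply_rigid(mb, fit)
  sqrt(mean(rowSums((ma - mb_fit)^2)))
}

#' Sieve a conformational ensemble by SHAPE compatibility
#'
#' Predicts the reactivity profile of every ensemble member, correlates it
#' with the observed profile (regular and noise-adjusted Pearson), computes
#' the heavy-atom RMSD to an optional reference, and ranks members by
#' noise-adjusted correlation (descending; ties broken by plain correlation,
#' then member id). Member failures are reported and excluded, never fatal.
#'
#' @param ensemble List of [rna_structure]s (names become member ids).
#' @param obs Observed [shape_profile()].
#' @param params Model parameters.
#' @param reference Optional reference [rna_structure] for RMSD.
#' @param mask Optional ligand mask (see [ligand_penalty()]).
#' @param noise Noise argument passed to [noise_adjusted_pearson()].
#' @return Tibble of class `shape_sieve`: `member_id`, `pc`, `na_pc`,
#'   `rmsd` (NA without a reference), `rank`.
#' @export
sieve <- function(ensemble, obs, params = default_params(),
                  reference = NULL, mask = NULL, noise = 0) {
  if (length(ensemble) == 0) abort("empty ensemble")
  ids <- names(ensemble)
  if (is.null(ids)) {
    ids <- map_chr(seq_along(ensemble), function(k) {
      s <- ensemble[[k]]
      if (inherits(s, "rna_structure")) s$source_name else paste0("member_", k)
    })
    ids <- make.unique(ids)
  }
  rows <- list()
  for (k in seq_along(ensemble)) {
    rec <- tryCatch({
      prediction <- predict_profile(ensemble[[k]], params = params,
                                    mask = mask)
      pp <- predicted_profile(prediction)
      tibble(
        member_id = ids[k],
        pc = pearson_cor(pp, obs),
        na_pc = noise_adjusted_pearson(pp, obs, noise = noise,
                                       epsilon = params$na_pc_epsilon %||% 0.01),
        rmsd = if (is.null(reference)) NA_real_ else
          rmsd_heavy(reference, ensemble[[k]]))
    }, error = function(e) {
      warn(paste0("sieve: member '", ids[k], "' failed: ",
                  conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1]] <- rec
  }
  if (length(rows) == 0) abort("sieve: every ensemble member failed")
  out <- bind_rows(rows) |>
    arrange(desc(.data$na_pc), desc(.data$pc), .data$member_id) |>
    mutate(rank = row_number())
  class(out) <- c("shape_sieve", class(out))
  out
}

#' Plot a sieve report
#'
#' Scatter of the regular and noise-adjusted correlations against RMSD when
#' a reference was supplied, otherwise correlations by rank.
#'
#' @param object A `shape_sieve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_sieve
#' @export
autoplot.shape_sieve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("pc", "na_pc"),
                              names_to = "statistic", values_to = "value")
  if (all(is.na(object$rmsd))) {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value,
                                       colour = .data$statistic)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "rank (by noise-adjusted PC)", y = "correlation") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$rmsd, y = .data$value,
                                       colour = .data$statistic)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "heavy-atom RMSD to reference (Å)",
                    y = "correlation") +
      ggplot2::theme_minimal()
  }
}
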
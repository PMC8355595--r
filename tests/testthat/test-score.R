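# The energy model: feature assembly and the reactivity combination.

hand_pairs <- function(...) {
  df <- tibble::tibble(...)
  if (!"base_i" %in% names(df)) df$base_i <- "G"
  if (!"base_j" %in% names(df)) df$base_j <- "C"
  if (!"pair_type" %in% names(df)) df$pair_type <- "cWW"
  if (!"is_canonical" %in% names(df)) df$is_canonical <- TRUE
  df
}

test_that("interaction energy sums scaled pair and polar stacking terms", {
  x <- fx$duplex_gggg   # 8 nucleotides; only the counts matter here
  params <- default_params()
  no_stacks <- detect_stacking(x)[0, ]

  # one pair of energy -3, A = 1, B = 0, no stacking
  params$A <- 1; params$B <- 0
  params$e_bp <- list(canonical = -3, default = -3)
  e <- interaction_energy(x, hand_pairs(i = 1L, j = 8L), no_stacks, params)
  expect_identical(e[1], -3)
  expect_identical(e[8], -3)
  # no pairs, no stacks: zero
  expect_identical(interaction_energy(x, hand_pairs(i = integer(0),
                                                    j = integer(0)),
                                      no_stacks, params),
                   rep(0, 8))
  # A = 0.5, B = 0.1, pair energy -2, stacks -1 (5') and -0.5 (3')
  params$A <- 0.5; params$B <- 0.1
  params$e_bp <- list(canonical = -2, default = -2)
  params$e_st_5p <- -1; params$e_st_3p <- -0.5
  stacks <- tibble::tibble(i = c(2L, 2L), k = c(1L, 3L),
                           polarity = c("5p", "3p"),
                           base_i = "G", base_k = c("G", "G"))
  e <- interaction_energy(x, hand_pairs(i = 2L, j = 7L), stacks, params)
  expect_equal(e[2], (0.5 * -2 + 0.1) + (-1) + (-0.5), tolerance = 1e-12)
})

test_that("stacking energies may be keyed by partner base", {
  x <- fx$duplex_gggg
  params <- default_params()
  params$e_st_5p <- list(G = -0.7, default = -0.1)
  params$e_st_3p <- -0.2
  stacks <- tibble::tibble(i = c(2L, 2L), k = c(1L, 3L),
                           polarity = c("5p", "5p"),
                           base_i = "G", base_k = c("G", "A"))
  e <- interaction_energy(x, hand_pairs(i = integer(0), j = integer(0)),
                          stacks, params)
  expect_equal(e[2], -0.7 + -0.1)
})

test_that("2D pairing energy is an indicator times the configured energy", {
  params <- default_params()
  params$e_2d_pair <- -1
  nested <- extract_secondary_structure(
    tibble::tibble(i = 1:3, j = c(9, 8, 7), is_canonical = TRUE, score = 1), 9)
  expect_equal(pairing_energy_2d(nested, params),
               c(-1, -1, -1, 0, 0, 0, -1, -1, -1))
  empty <- extract_secondary_structure(
    tibble::tibble(i = integer(0), j = integer(0), is_canonical = logical(0),
                   score = numeric(0)), 4)
  expect_equal(pairing_energy_2d(empty, params), rep(0, 4))
  # pseudoknotted pairs count only when configured to
  pk <- extract_secondary_structure(
    tibble::tibble(i = c(1, 3), j = c(6, 9), is_canonical = TRUE,
                   score = 1:2), 9)
  with_pk <- pairing_energy_2d(pk, params)
  expect_equal(sum(with_pk != 0), 4)
  params$include_pseudoknots <- FALSE
  without_pk <- pairing_energy_2d(pk, params)
  expect_equal(sum(without_pk != 0), 2)
})

test_that("neighbor smoothing follows the asymmetric four-point window", {
  v <- c(10, 20, 30, 40)
  # delta weights reproduce the input
  expect_equal(smooth_profile(v, c(0, 1, 0, 0)), v)
  # uniform weights give the windowed mean at interior positions
  expect_equal(smooth_profile(c(1, 2, 3, 4, 9), c(1, 1, 1, 1))[2], 2.5)
  # weighted case evaluated by hand: window {1,2,3,4} at i = 2
  expect_equal(smooth_profile(v, c(1, 2, 1, 0))[2],
               (1 * 10 + 2 * 20 + 1 * 30 + 0 * 40) / 4)
  # boundary truncation renormalizes over retained weights
  w <- c(1, 2, 1, 1)
  expect_equal(smooth_profile(v, w)[1],
               (2 * 10 + 1 * 20 + 1 * 30) / 4)
  expect_equal(smooth_profile(v, w)[4],
               (1 * 30 + 2 * 40) / 3)
  expect_error(smooth_profile(v, c(0, 0, 0, 0)), "positive sum")
})

test_that("smoothing never crosses chain breaks", {
  v <- c(1, 1, 1, 100, 100, 100)
  out <- smooth_profile(v, c(1, 1, 1, 1), breaks = 3L)
  expect_equal(out, c(1, 1, 1, 100, 100, 100))
})

test_that("terminal factors apply per chain at the configured depths", {
  params <- default_params()
  params$f_term <- 2.0
  expect_equal(terminal_factor(5L, params), c(2, 1, 1, 1, 2))
  params$f_term <- 1.0
  expect_equal(terminal_factor(5L, params), rep(1, 5))
  params$f_term <- 2.0
  expect_equal(terminal_factor(c(3L, 3L), params), c(2, 1, 2, 2, 1, 2))
  params$f_term <- c(3, 1.5)
  expect_equal(terminal_factor(6L, params), c(3, 1.5, 1, 1, 1.5, 3))
})

test_that("ligand penalties follow the mask and reject malformed input", {
  params <- default_params()
  params$e_lig <- -2
  expect_equal(ligand_penalty(NULL, 10, params), rep(0, 10))
  expect_equal(ligand_penalty(c(0, 1, 0), 3, params), c(0, -2, 0))
  expect_error(ligand_penalty(c(0, 2, 0), 3, params), "entry 2")
  expect_error(ligand_penalty(c(0, 1), 3, params), "length")
})

test_that("an unpaired, unstacked strand reduces to the surface term", {
  spacing <- 9
  tmpl <- shapesieve:::template_residue("A")
  res <- lapply(1:4, function(k) {
    t2 <- tmpl
    t2$x <- t2$x + spacing * k
    t2
  })
  x <- shapesieve:::assemble_structure(res, chains = rep("A", 4),
                                       resnos = 1:4, resnames = rep("A", 4),
                                       source_name = "free_strand")
  params <- default_params()
  params$f_term <- 1.0
  params$f_sug <- list(other = 1.0)
  pred <- predict_profile(x, params)
  f <- tidy(pred)
  expect_equal(f$e_ie, rep(0, 4))
  expect_equal(f$e_2d, rep(0, 4))
  expect_equal(f$se, rep(0, 4))
  expect_equal(f$p, f$a_sas_bar + params$a_sas0, tolerance = 1e-12)
})

test_that("the prediction obeys p = SF * exp(SE) and stays nonnegative", {
  pred <- predict_profile(fx$hairpin4)
  f <- tidy(pred)
  expect_equal(f$p, f$sf * exp(f$se), tolerance = 1e-12)
  expect_true(all(f$p >= 0))
  expect_true(all(f$sf >= 0))
})

test_that("stem positions are predicted less reactive than loop positions", {
  f <- tidy(predict_profile(fx$hairpin4))
  stem <- c(1:4, 9:12)
  loop <- 5:8
  expect_lt(mean(f$p[stem]), mean(f$p[loop]))
})

test_that("masking a nucleotide suppresses reactivity exactly there", {
  params <- default_params()
  mask <- rep(0, 12)
  mask[6] <- 1
  base <- tidy(predict_profile(fx$hairpin4, params))
  masked <- tidy(predict_profile(fx$hairpin4, params, mask = mask))
  expect_lt(masked$p[6], base$p[6])
  expect_equal(masked$p[-6], base$p[-6], tolerance = 1e-12)
})

test_that("strengthening pairing interactions never increases reactivity", {
  weak <- default_params()
  weak$e_bp <- list(canonical = 0, default = 0)
  weak$e_2d_pair <- 0
  strong <- default_params()   # canonical -1, e_2d -0.5
  suppressWarnings({
    p_weak <- tidy(predict_profile(fx$hairpin4, weak))$p
  })
  p_strong <- tidy(predict_profile(fx$hairpin4, strong))$p
  expect_true(all(p_strong <= p_weak + 1e-12))
})

test_that("the full pipeline is deterministic", {
  a <- tidy(predict_profile(fx$hairpin3))
  b <- tidy(predict_profile(fx$hairpin3))
  expect_identical(a, b)
})

test_that("model parameters round-trip through the YAML config", {
  params <- default_params()
  params$A <- 1.25
  params$e_bp <- list(canonical = -1.1, `cWH` = -0.3, default = -0.4)
  params$f_term <- c(2.5, 1.2)
  tf <- tempfile(fileext = ".yaml")
  write_params(params, tf)
  back <- read_params(tf)
  expect_equal(unclass(back)[order(names(back))],
               unclass(params)[order(names(params))], tolerance = 1e-12)
})

test_that("parameter validation catches malformed configs", {
  p <- unclass(default_params())
  p$w <- c(0, 0, 0, 0)
  expect_error(shapesieve:::validate_params(p), "positive sum")
  p <- unclass(default_params())
  p$f_term <- -1
  expect_error(shapesieve:::validate_params(p), "f_term")
  p <- unclass(default_params())
  p$e_2d_pair <- 0.5
  expect_warning(shapesieve:::validate_params(p), "positive")
})
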
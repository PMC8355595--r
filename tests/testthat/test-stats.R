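# Profile IO, correlations, RMSD, and ensemble sieving.

test_that("SHAPE files parse with the -999 missing sentinel", {
  tf <- tempfile(fileext = ".shape")
  writeLines(c("# comment", "1 0.5", "2 -999", "3 1.2"), tf)
  prof <- read_shape(tf)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$missing, c(FALSE, TRUE, FALSE))
  expect_equal(prof$reactivity[c(1, 3)], c(0.5, 1.2))
})

test_that("malformed SHAPE files fail with the offending line", {
  tf <- tempfile(fileext = ".shape")
  writeLines(character(0), tf)
  expect_error(read_shape(tf), "empty")
  writeLines(c("1 0.5", "1 0.6"), tf)
  expect_error(read_shape(tf), "duplicate index 1")
  writeLines(c("1 0.5", "2 abc"), tf)
  expect_error(read_shape(tf), "line 2")
  writeLines(c("1"), tf)
  expect_error(read_shape(tf), "line 1")
})

test_that("profile positions can be offset to match structure numbering", {
  tf <- tempfile(fileext = ".shape")
  writeLines(c("17 0.5", "18 0.7", "19 0.9"), tf)
  prof <- read_shape(tf, offset = -16L)
  expect_equal(prof$position, 1:3)
})

test_that("mask files accept both one- and two-column dialects", {
  tf <- tempfile()
  writeLines(c("0", "1", "0"), tf)
  expect_equal(read_mask(tf, 3), c(0L, 1L, 0L))
  writeLines(c("2 1"), tf)
  expect_equal(read_mask(tf, 3), c(0L, 1L, 0L))
  writeLines(c("2 2"), tf)
  expect_error(read_mask(tf, 3), "0 or 1")
  writeLines(c("9 1"), tf)
  expect_error(read_mask(tf, 3), "outside")
})

test_that("Pearson correlation matches the product-moment formula", {
  pred <- shape_profile(1:4, c(1, 2, 3, 4))
  obs <- shape_profile(1:4, c(1.1, 1.9, 3.2, 3.8))
  expect_equal(pearson_cor(pred, pred), 1)
  anti <- shape_profile(1:4, -c(1, 2, 3, 4) + 5)
  expect_equal(pearson_cor(pred, anti), -1)
  x <- pred$reactivity; y <- obs$reactivity
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(pred, obs), hand, tolerance = 1e-12)
  # missing positions are excluded
  obs2 <- shape_profile(1:4, c(1.1, -999, 3.2, 3.8))
  keep <- c(1, 3, 4)
  expect_equal(pearson_cor(pred, obs2),
               stats::cor(x[keep], y[keep]), tolerance = 1e-12)
  expect_error(pearson_cor(shape_profile(1:2, c(1, 2)),
                           shape_profile(1:2, c(2, 1))), "fewer than 3")
  expect_error(pearson_cor(shape_profile(1:3, c(1, 1, 1)),
                           shape_profile(1:3, c(1, 2, 3))), "zero variance")
})

test_that("correlations are invariant under positive affine / scale changes", {
  pred <- shape_profile(1:6, c(0.2, 1.4, 0.9, 2.2, 0.1, 1.7))
  obs <- shape_profile(1:6, c(0.3, 1.1, 1.0, 2.5, 0.2, 1.4))
  expect_equal(pearson_cor(shape_profile(1:6, 2 * pred$reactivity + 3), obs),
               pearson_cor(pred, obs), tolerance = 1e-12)
  # na_pc with epsilon = 0: pure scaling is absorbed by log centering
  expect_equal(
    noise_adjusted_pearson(shape_profile(1:6, 5 * pred$reactivity), obs,
                           epsilon = 0),
    noise_adjusted_pearson(pred, obs, epsilon = 0), tolerance = 1e-12)
})

test_that("noise-adjusted correlation has its declared limits", {
  pred <- shape_profile(1:6, c(0.2, 1.4, 0.9, 2.2, 0.1, 1.7))
  obs <- shape_profile(1:6, c(0.3, 1.1, 1.0, 2.5, 0.2, 1.4))
  expect_equal(noise_adjusted_pearson(pred, pred), 1)
  # zero noise: plain correlation of the log-profiles
  eps <- 0.01
  expect_equal(noise_adjusted_pearson(pred, obs, noise = 0, epsilon = eps),
               stats::cor(log(pred$reactivity + eps),
                          log(obs$reactivity + eps)), tolerance = 1e-12)
  # an infinite-noise position is equivalent to deleting it
  noise <- c(0, 0, Inf, 0, 0, 0)
  dropped <- shape_profile(c(1, 2, 4, 5, 6), pred$reactivity[-3])
  obs_dropped <- shape_profile(c(1, 2, 4, 5, 6), obs$reactivity[-3])
  expect_equal(noise_adjusted_pearson(pred, obs, noise = noise),
               noise_adjusted_pearson(dropped, obs_dropped),
               tolerance = 1e-12)
  # small negative reactivities are clamped, deep negatives are missing
  obs_neg <- shape_profile(1:6, c(-0.05, 1.1, 1.0, 2.5, 0.2, 1.4))
  obs_clamped <- shape_profile(1:6, c(0, 1.1, 1.0, 2.5, 0.2, 1.4))
  expect_equal(noise_adjusted_pearson(pred, obs_neg),
               noise_adjusted_pearson(pred, obs_clamped), tolerance = 1e-12)
})

test_that("both correlations stay within [-1, 1] on random profiles", {
  draws <- withr::with_seed(99, {
    lapply(1:50, function(k) {
      n <- sample(5:30, 1)
      list(a = stats::rlnorm(n), b = stats::rlnorm(n),
           noise = stats::runif(n, 0, 2))
    })
  })
  for (d in draws) {
    n <- length(d$a)
    pa <- shape_profile(1:n, d$a)
    pb <- shape_profile(1:n, d$b)
    pc <- pearson_cor(pa, pb)
    napc <- noise_adjusted_pearson(pa, pb, noise = d$noise)
    expect_true(pc >= -1 - 1e-12 && pc <= 1 + 1e-12)
    expect_true(napc >= -1 - 1e-12 && napc <= 1 + 1e-12)
  }
})

test_that("heavy-atom RMSD is zero under rigid motion and symmetric", {
  a <- fx$hairpin3
  expect_equal(rmsd_heavy(a, a), 0)
  moved <- transform_structure(a, rotation_about_z(37), trans = c(5, -3, 2))
  expect_lt(rmsd_heavy(a, moved), 1e-9)
  b <- perturb_structure(a, 1.0, seed = 13)
  expect_equal(rmsd_heavy(a, b), rmsd_heavy(b, a), tolerance = 1e-12)
})

test_that("Kabsch RMSD agrees with an independent quaternion superposition", {
  a <- fx$hairpin3
  for (seed in c(5, 6, 7)) {
    b <- perturb_structure(a, 1.0, seed = seed)
    b <- transform_structure(b, seeded_random_rotation(seed + 50),
                             trans = c(2, 9, -4))
    ours <- rmsd_heavy(a, b)
    oracle <- quaternion_rmsd(as.matrix(a$atoms[, c("x", "y", "z")]),
                              as.matrix(b$atoms[, c("x", "y", "z")]))
    expect_lt(abs(ours - oracle), 1e-9)
  }
})

test_that("RMSD grows with perturbation strength on average", {
  a <- fx$hairpin3
  cmp <- vapply(1:20, function(seed) {
    rmsd_heavy(a, perturb_structure(a, 2.0, seed = seed)) >
      rmsd_heavy(a, perturb_structure(a, 0.5, seed = seed + 1000))
  }, logical(1))
  expect_gte(sum(cmp), 19)
})

test_that("sieve ranks members deterministically with full bookkeeping", {
  native <- fx$hairpin4
  obs <- synth_shape(native, noise_sigma = 0.1, seed = 21)
  single <- sieve(list(native = native), obs)
  expect_equal(single$rank, 1L)
  expect_equal(single$member_id, "native")

  decoys <- lapply(1:5, function(k) scramble_2d_decoy(native, seed = k))
  names(decoys) <- paste0("decoy", 1:5)
  ens <- c(list(native = native), decoys)
  report <- sieve(ens, obs, reference = native)
  expect_s3_class(report, "shape_sieve")
  expect_equal(nrow(report), 6)
  expect_setequal(report$rank, 1:6)
  expect_equal(report$na_pc, sort(report$na_pc, decreasing = TRUE))
  expect_equal(report$rmsd[report$member_id == "native"], 0, tolerance = 1e-9)
  expect_true(all(report$rmsd[report$member_id != "native"] > 3))
  report2 <- sieve(ens, obs, reference = native)
  expect_identical(as.data.frame(report), as.data.frame(report2))
})

test_that("failing ensemble members are excluded, never fatal", {
  native <- fx$hairpin4
  obs <- synth_shape(native, noise_sigma = 0.1, seed = 22)
  # a two-nucleotide member cannot reach 3 jointly observed positions
  broken <- build_duplex("G")
  ens <- list(native = native, broken = broken)
  expect_warning(report <- sieve(ens, obs), "broken")
  expect_equal(nrow(report), 1)
  expect_equal(report$member_id, "native")
})
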
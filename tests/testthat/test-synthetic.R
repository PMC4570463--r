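test_that("zero noise reproduces the model curves exactly and the same seed
           is bit-identical", {
  st <- generate_bmp_study(noise_sd_rel = 0, seed = 5,
                           configs = study_configs(is_ratios = 1,
                                                   ca_ratios = c(0, 0.5)))
  expect_true(all(st$ok))
  for (i in seq_along(st$configs)) {
    expect_identical(st$curves[[i]],
                     methane_curve(st$trajectories[[i]], st$conversions))
  }
  st_a <- generate_bmp_study(noise_sd_rel = 0.05, seed = 9,
                             configs = study_configs(is_ratios = 0.4,
                                                     ca_ratios = 0))
  st_b <- generate_bmp_study(noise_sd_rel = 0.05, seed = 9,
                             configs = study_configs(is_ratios = 0.4,
                                                     ca_ratios = 0))
  expect_identical(st_a$curves, st_b$curves)
  expect_false(identical(
    st_a$curves,
    generate_bmp_study(noise_sd_rel = 0.05, seed = 10,
                       configs = study_configs(is_ratios = 0.4,
                                               ca_ratios = 0))$curves))
})

test_that("generated curves are non-negative and non-decreasing even at
           high noise", {
  st <- generate_bmp_study(noise_sd_rel = 0.8, seed = 3,
                           configs = study_configs(is_ratios = c(0.1, 1.0),
                                                   ca_ratios = 0))
  for (cv in st$curves[st$ok]) {
    expect_true(all(cv$cumulative_CH4_L_per_L >= 0))
    expect_true(all(diff(cv$cumulative_CH4_L_per_L) >= 0))
  }
  expect_error(generate_bmp_study(noise_sd_rel = -0.1), "non-negative")
})

test_that("clipped increment noise is unbiased at the working noise level", {
  # Monte-Carlo oracle on one noiseless curve: re-noise its increments 1000
  # times and compare the mean final volume with the noiseless final.
  st <- generate_bmp_study(noise_sd_rel = 0, seed = 2,
                           configs = study_configs(is_ratios = 0.4,
                                                   ca_ratios = 0.5))
  inc <- diff(st$curves[[1]]$cumulative_CH4_L_per_L)
  final0 <- sum(inc)
  set.seed(77)
  finals <- replicate(1000,
    sum(pmax(0, inc * (1 + rnorm(length(inc), 0, 0.05)))))
  expect_lt(abs(mean(finals) - final0) / final0, 0.01)
})

test_that("noiseless final methane never decreases with inoculum at fixed
           calcium and substrate", {
  st <- generate_bmp_study(noise_sd_rel = 0, seed = 1)
  finals <- vapply(st$curves, function(cv)
    cv$cumulative_CH4_L_per_L[nrow(cv)], numeric(1))
  key <- vapply(st$configs, function(cf)
    paste(cf$substrate$name, cf$config$ca_ratio), character(1))
  isr <- vapply(st$configs, function(cf) cf$config$is_ratio, numeric(1))
  for (idx in split(seq_along(finals), key)) {
    expect_true(all(diff(finals[idx][order(isr[idx])]) >= -1e-9))
  }
})

test_that("the RNG state of the caller is left untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_bmp_study(noise_sd_rel = 0.05, seed = 4,
                               configs = study_configs(is_ratios = 0.1,
                                                       ca_ratios = 0)))
  expect_identical(.Random.seed, before)
})

test_that("studies round-trip to disk as curves + manifest + truth", {
  st <- generate_bmp_study(noise_sd_rel = 0.05, seed = 8,
                           configs = study_configs(is_ratios = c(0.4, 1.0),
                                                   ca_ratios = 0))
  dir <- withr::local_tempdir()
  manifest <- write_study(st, dir)
  expect_true(file.exists(file.path(dir, "true_params.yml")))
  ds <- read_manifest(manifest)
  expect_length(ds, 4)
  expect_identical(ds[[1]]$curve$cumulative_CH4_L_per_L,
                   st$curves[[1]]$cumulative_CH4_L_per_L)
  expect_equal(unclass(read_params(file.path(dir, "true_params.yml"))),
               unclass(st$true_params), tolerance = 1e-12)
})
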
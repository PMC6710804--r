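test_that("a phantom without reflectors yields pure noise / an all-zero A-scan", {
  cfg0 <- noiseless_config()
  s <- simulate_spectrum(dark_phantom(), 0, -0.3, cfg0)
  expect_true(all(s == 0))
  a <- reconstruct_ascan(s, cfg0)
  expect_true(all(a$amplitudes == 0))
  # with noise enabled the spectrum is nonzero but carries no fringe energy
  cfg <- sim_config()
  withr::with_seed(1, {
    s2 <- simulate_spectrum(dark_phantom(), 0, -0.3, cfg)
  })
  expect_gt(sd(s2), 0)
})

test_that("FFT depth mapping places a single reflector at the expected pixel", {
  cfg0 <- noiseless_config()
  # reflector 1.000 mm (optical) below the gate
  spec <- healthy_eye_spec()
  spec$media$reflectivity <- c(1, 0, 0, 0)
  spec$retina$rpe_reflectivity <- 0
  ph <- build_phantom(spec)
  gate <- -1.0  # cornea_front (optical depth 0) sits 1.000 mm below the gate
  env <- reconstruct_ascan(simulate_spectrum(ph, 0, gate, cfg0), cfg0)$amplitudes
  peak_px <- which.max(env) - 1
  expect_lte(abs(peak_px - 1000 / cfg0$axial_pixel_um), 1)
})

test_that("two reflectors 20 um apart are resolved as two envelope maxima", {
  cfg0 <- noiseless_config()
  N <- cfg0$spectral_samples
  k <- 0:(N - 1)
  f1 <- 1000 / cfg0$axial_pixel_um          # 1.000 mm
  f2 <- 1020 / cfg0$axial_pixel_um          # 1.020 mm
  s <- cos(2 * pi * f1 * k / N) + cos(2 * pi * f2 * k / N)
  env <- reconstruct_ascan(s, cfg0)$amplitudes
  pk <- pracma::findpeaks(env, minpeakheight = 0.3)
  expect_equal(nrow(pk), 2)
})

test_that("point-reflector envelope FWHM respects the axial resolution", {
  cfg0 <- noiseless_config()
  N <- cfg0$spectral_samples
  f <- 420   # exact depth bin (1.008 mm): the canonical on-bin FWHM case
  env <- reconstruct_ascan(cos(2 * pi * f * (0:(N - 1)) / N), cfg0)$amplitudes
  above <- which(env >= max(env) / 2)
  # linear-interpolated full width at half maximum, in tissue um
  lo <- min(above); hi <- max(above)
  frac_lo <- (env[lo] - max(env) / 2) / (env[lo] - env[lo - 1])
  frac_hi <- (env[hi] - max(env) / 2) / (env[hi] - env[hi + 1])
  fwhm_px <- (hi + frac_hi) - (lo - frac_lo)
  expect_lte(fwhm_px * cfg0$axial_pixel_um, cfg0$axial_resolution_um)
})

test_that("reconstruction preserves spectral energy in the envelope", {
  cfg0 <- noiseless_config()
  N <- cfg0$spectral_samples
  withr::with_seed(11, s <- rnorm(N))
  w <- boct:::hann_window(N)
  F <- fft(s * w)
  env <- reconstruct_ascan(s, cfg0)$amplitudes          # bins 0 .. N/2 - 1
  scale <- (2 / sum(w))^2
  lhs <- sum(env^2) * 2 - Mod(F[1])^2 * scale + Mod(F[N / 2 + 1])^2 * scale
  expect_equal(lhs, N * sum((s * w)^2) * scale, tolerance = 1e-6)
})

test_that("simulated peak depth is linear in true optical depth (roll-off sweep)", {
  cfg0 <- noiseless_config()
  spec <- healthy_eye_spec()
  spec$media$reflectivity <- c(1, 0, 0, 0)
  spec$retina$rpe_reflectivity <- 0
  ph <- build_phantom(spec)
  gates <- seq(-2.2, -0.3, by = 0.1)   # reflector at depth -gate below pixel 0
  px <- vapply(gates, function(g) {
    env <- reconstruct_ascan(simulate_spectrum(ph, 0, g, cfg0), cfg0)$amplitudes
    which.max(env) - 1
  }, numeric(1))
  fit <- lm(px ~ gates)
  expect_gt(summary(fit)$r.squared, 0.9999)
  expect_equal(unname(coef(fit)[2]), -1000 / cfg0$axial_pixel_um, tolerance = 1e-3)
})

test_that("opacity shadowing attenuates only posterior reflectors", {
  clean <- build_phantom()
  shaded <- posterior_capsule_opacity_phantom(0.95)
  r0 <- boct:::phantom_reflectors(clean, 0)
  r1 <- boct:::phantom_reflectors(shaded, 0)
  ant <- r1$id != "retina_post"
  expect_identical(r1[ant, ], r0[ant, ])
  expect_equal(r0$amplitude[r0$id == "retina_post"] /
                 r1$amplitude[r1$id == "retina_post"], 20, tolerance = 1e-12)
  # anterior windows are bit-identical with and without the opacity
  cfg0 <- noiseless_config()
  w_clean <- acquire_window(clean, 1, config = cfg0, seed = 5)
  w_shaded <- acquire_window(shaded, 1, config = cfg0, seed = 5)
  expect_identical(w_clean$ascans, w_shaded$ascans)
})

test_that("retinal peak under a dense opacity drops at least 20-fold", {
  cfg0 <- noiseless_config()
  w_clean <- acquire_window(build_phantom(), 4, config = cfg0, seed = 1)
  w_shade <- acquire_window(posterior_capsule_opacity_phantom(0.95), 4,
                            config = cfg0, seed = 1)
  expect_gt(max(w_clean$ascans) / max(w_shade$ascans), 20 * (1 - 1e-9))
})

test_that("acquisitions are bit-reproducible under a fixed seed", {
  ph <- build_phantom()
  cfg <- sim_config()
  expect_identical(acquire_window(ph, 2, config = cfg, seed = 42),
                   acquire_window(ph, 2, config = cfg, seed = 42))
  expect_identical(acquire_measurement(ph, cfg, seed = 42),
                   acquire_measurement(ph, cfg, seed = 42))
})

test_that("alignment jitter has the configured scale and vanishes at SD 0", {
  ph <- build_phantom()
  cfg <- sim_config()
  jit <- unlist(lapply(1:10, function(i)
    acquire_measurement(ph, cfg, seed = 100 + i)$jitter$jitter_um))
  expect_equal(length(jit), 80)
  # chi-square 99.9% coverage band for the sample SD at df = 79
  band <- cfg$jitter_sd_um * sqrt(qchisq(c(5e-4, 1 - 5e-4), 79) / 79)
  expect_gt(sd(jit), band[1])
  expect_lt(sd(jit), band[2])

  cfg0 <- noiseless_config()
  s1 <- acquire_measurement(ph, cfg0, seed = 1)
  s2 <- acquire_measurement(ph, cfg0, seed = 2)
  expect_equal(s1$windows$horizontal[[1]]$ascans, s2$windows$horizontal[[1]]$ascans)
})

test_that("a window that cannot hold its structure fails without spoiling the shot", {
  spec <- healthy_eye_spec()
  spec$media$thickness_mm[1] <- 1.5    # cornea too thick for one window
  spec$media$thickness_mm[2] <- 2.09   # keep ACD at the mean
  ph <- build_phantom(spec)
  expect_error(acquire_window(ph, 1, config = sim_config()), "cannot fit")
  shot <- acquire_measurement(ph, sim_config(), seed = 1)
  expect_false(shot$ok)
  expect_true(all(shot$jitter$failed[shot$jitter$role == 1]))
  expect_true(all(!shot$jitter$failed[shot$jitter$role != 1]))
  expect_s3_class(shot$windows$horizontal[[4]], "bscan_window")
})
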
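test_that("reshape_raw is shape-correct, lossless and validates divisibility", {
  cfg <- radar_config()
  n <- 2 * 3 * 8 * 128
  v <- sin(seq_len(n)) * 0.5
  cube <- reshape_raw(v, cfg)
  expect_equal(dim(cube$values), c(2, 3, 8, 128))
  expect_identical(flatten_cube(cube), v)
  expect_error(reshape_raw(v[1:100], cfg), "not divisible")
})

test_that("a pure fast-time cosine concentrates at its bin", {
  cfg <- small_config()
  ns <- cfg$n_samples_per_chirp
  chirp <- 0.5 * cos(2 * pi * 7 * (0:(ns - 1)) / ns)
  v <- array(rep(chirp, each = 4 * 2 * 8),
             dim = c(4, 2, 8, ns))
  for (f in 1:4) for (a in 1:2) for (ch in 1:8) v[f, a, ch, ] <- chirp
  prof <- range_fft(radar_cube(v, cfg))
  mag <- Mod(prof$values[1, 1, ])
  expect_equal(which.max(mag) - 1L, 7L)
  expect_gt(mag[8], 100 * max(mag[-8]))
})

test_that("chirp averaging is a no-op on a noise-free static target", {
  cfg <- radar_config()
  traj <- displacement_trajectory(cfg$frame_rate, rep(0, 6))
  sc <- scene_spec(noise_snr_db = Inf, aux_snr_db = Inf)
  cube <- simulate_frames(cfg, traj, sc, seed = 1)
  pa <- range_fft(cube, average_chirps = TRUE)
  pf <- range_fft(cube, average_chirps = FALSE)
  expect_equal(pa$values, pf$values, tolerance = 1e-12)
})

test_that("averaging over chirps reduces the noise-floor variance by about Nc", {
  cfg <- small_config()
  nc <- cfg$n_chirps_per_frame
  n_frames <- 3000L
  set.seed(71)
  v <- array(stats::rnorm(n_frames * 2 * nc * cfg$n_samples_per_chirp, sd = 0.2),
             dim = c(n_frames, 2, nc, cfg$n_samples_per_chirp))
  cube <- radar_cube(v / max(abs(v)), cfg)
  single <- range_fft(cube, average_chirps = FALSE)
  avg <- range_fft(cube, average_chirps = TRUE)
  # variance of the mean of Nc independent spectra is 1/Nc of one spectrum's
  bin <- 6L
  ratio <- stats::var(Re(single$values[, 1, bin])) /
    stats::var(Re(avg$values[, 1, bin]))
  expect_equal(ratio, nc, tolerance = 0.15 * nc)
})

test_that("unknown window names are rejected, hann is accepted", {
  cfg <- small_config()
  cube <- radar_cube(array(0.1, dim = c(2, 2, 8, 32)), cfg)
  expect_error(range_fft(cube, window = "blackman"), "unknown window")
  expect_silent(range_fft(cube, window = "hann"))
})

test_that("bin selection takes the first qualifying spike, never DC", {
  cfg <- radar_config()
  traj <- displacement_trajectory(cfg$frame_rate, rep(0, 4))
  sc <- scene_spec(base_range = bin_centred_range(cfg, 11),
                   noise_snr_db = Inf, aux_snr_db = Inf)
  prof <- range_fft(simulate_frames(cfg, traj, sc, seed = 1))
  expect_identical(select_target_bin(prof), 11L)

  # two targets: the first (weaker) spike wins over the stronger one
  fake <- prof
  mag_template <- numeric(dim(prof$values)[3])
  mag_template[5 + 1] <- 2
  mag_template[20 + 1] <- 10
  fake$values <- array(rep(mag_template, each = prod(dim(prof$values)[1:2])),
                       dim = dim(prof$values))
  expect_identical(select_target_bin(fake), 5L)

  # flat spectrum: no local maximum clears the prominence floor
  flat <- prof
  flat$values <- array(1 + 0i, dim = dim(prof$values))
  expect_error(select_target_bin(flat), "no range peak")
})

test_that("bin selection is identical across frames of the default scene", {
  cfg <- radar_config()
  traj <- synth_jvp_trajectory(jvp_waveform_spec(), 2, cfg$frame_rate, seed = 3)
  prof <- range_fft(simulate_frames(cfg, traj, scene_spec(), seed = 3))
  bins <- vapply(seq_len(dim(prof$values)[1]), function(f) {
    sub <- prof
    sub$values <- prof$values[f, , , drop = FALSE]
    select_target_bin(sub)
  }, integer(1))
  expect_true(all(bins == bins[1]))
})

test_that("extracted I/Q is constant for a static target and swings 4 pi d0 / lambda for a vibrating one", {
  cfg <- radar_config()
  sc <- scene_spec(base_range = bin_centred_range(cfg, 4),
                   noise_snr_db = Inf, aux_snr_db = Inf)
  static <- displacement_trajectory(cfg$frame_rate, rep(0, 50))
  iq <- extract_iq(range_fft(simulate_frames(cfg, static, sc, seed = 1)), 4)
  expect_lt(max(Mod(iq$values[, 1] - iq$values[1, 1])), 1e-9 * Mod(iq$values[1, 1]))

  d0 <- 100e-6
  t <- (0:499) / cfg$frame_rate
  vib <- displacement_trajectory(cfg$frame_rate, d0 * sin(2 * pi * 1.5 * t))
  iq2 <- extract_iq(range_fft(simulate_frames(cfg, vib, sc, seed = 1)), 4)
  ph <- signal::unwrap(Arg(iq2$values[, 1]))
  swing <- (max(ph) - min(ph)) / 2
  expect_equal(swing, 4 * pi * d0 / wavelength(cfg), tolerance = 0.05)
})

test_that("inter-antenna phase difference follows the steering convention", {
  cfg <- radar_config()
  for (alpha in c(-25, 10, 30)) {
    sc <- scene_spec(base_range = bin_centred_range(cfg, 4), doa = alpha,
                     noise_snr_db = Inf, aux_snr_db = Inf)
    traj <- displacement_trajectory(cfg$frame_rate, rep(0, 5))
    iq <- extract_iq(range_fft(simulate_frames(cfg, traj, sc, seed = 1)), 4)
    dphi <- Arg(iq$values[1, 2] * Conj(iq$values[1, 1]))
    expect_equal(dphi, -pi * sin(alpha * pi / 180), tolerance = 1e-6)
  }
})

test_that("scaling the cube scales magnitudes linearly and leaves phases unchanged", {
  cfg <- radar_config()
  traj <- synth_jvp_trajectory(jvp_waveform_spec(), 1, cfg$frame_rate, seed = 2)
  cube <- simulate_frames(cfg, traj, scene_spec(), seed = 2)
  half <- radar_cube(cube$values * 0.5, cfg)
  p1 <- range_fft(cube)
  p2 <- range_fft(half)
  expect_equal(Mod(p2$values), Mod(p1$values) * 0.5, tolerance = 1e-12)
  keep <- Mod(p1$values) > 1e-9 * max(Mod(p1$values))
  expect_equal(Arg(p2$values)[keep], Arg(p1$values)[keep], tolerance = 1e-9)
})

test_that("fast-time spectral energy matches chirp energy (Parseval, no window)", {
  cfg <- small_config()
  ns <- cfg$n_samples_per_chirp
  set.seed(8)
  chirp <- stats::rnorm(ns, sd = 0.2)
  v <- array(0, dim = c(1, 2, 8, ns))
  for (a in 1:2) for (ch in 1:8) v[1, a, ch, ] <- chirp
  # oracle: full-FFT Parseval on the demeaned chirp
  cd <- chirp - mean(chirp)
  full <- Mod(stats::fft(cd))^2
  expect_equal(sum(full) / ns, sum(cd^2), tolerance = 1e-12)
  # the one-sided profile carries the same energy once negative bins are counted
  prof <- range_fft(radar_cube(v, cfg))
  m2 <- Mod(prof$values[1, 1, ])^2
  one_sided <- m2[1] + 2 * sum(m2[2:(ns / 2)]) + m2[ns / 2 + 1]
  expect_equal(one_sided / ns, sum(cd^2), tolerance = 1e-9)
})

test_that("antenna selection ranks by displacement-band SNR", {
  cfg <- radar_config()
  t <- (0:749) / cfg$frame_rate
  traj <- displacement_trajectory(cfg$frame_rate, 100e-6 * sin(2 * pi * 1.5 * t))
  sc <- scene_spec(base_range = bin_centred_range(cfg, 4),
                   noise_snr_db = Inf, aux_snr_db = Inf)
  cube <- simulate_frames(cfg, traj, sc, seed = 6)

  # three identical channels: tie broken towards the lowest indices
  iq <- extract_iq(range_fft(cube), 4)
  tie <- select_antennas(iq)
  expect_identical(tie$pair, c(1L, 2L))

  # a pure-noise channel is never selected
  set.seed(33)
  noisy <- iq
  noisy$values[, 2] <- complex(real = stats::rnorm(750), imaginary = stats::rnorm(750))
  sel <- select_antennas(noisy)
  expect_false(2L %in% sel$pair)

  # deliberately degraded third channel (default aux_snr_db) -> pair (1, 2)
  sc2 <- scene_spec(base_range = bin_centred_range(cfg, 4),
                    noise_snr_db = 40, aux_snr_db = 10)
  cube2 <- simulate_frames(cfg, traj, sc2, seed = 6)
  sel2 <- select_antennas(extract_iq(range_fft(cube2), 4))
  expect_identical(sel2$pair, c(1L, 2L))
  expect_gt(min(sel2$snr_db[1:2]), sel2$snr_db[3])
})
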
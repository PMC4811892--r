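test_that("Greenwood map matches its closed form and inverts", {
  m <- greenwood_map()
  expect_equal(greenwood_frequency(0, m), 165.4 * (1 - 0.88))
  expect_equal(greenwood_frequency(1, m), 165.4 * (10^2.1 - 0.88))
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(greenwood_frequency(x, m)) > 0))
  f <- c(100, 250, 1000, 4000, 10000)
  expect_equal(greenwood_frequency(greenwood_position(f, m), m), f,
               tolerance = 1e-9)
  expect_equal(greenwood_position(greenwood_frequency(0.5, m), m), 0.5,
               tolerance = 1e-9)
  expect_lt(greenwood_position(100, m), greenwood_position(10000, m))
  expect_error(greenwood_frequency(-0.1, m), "position")
  expect_error(greenwood_frequency(1.2, m), "position")
  expect_error(greenwood_position(-1000, m), "domain")
})

test_that("filterbank spans the range with equal basilar-membrane spacing", {
  m <- greenwood_map()
  fb1 <- design_filterbank(vocoder_config(n_channels = 1), m)
  expect_equal(fb1$edges, c(100, 10000))
  fb <- design_filterbank(vocoder_config(), m)
  expect_length(fb$edges, 9)
  expect_length(fb$centers, 8)
  expect_true(all(diff(fb$edges) > 0))
  incr <- diff(greenwood_position(fb$edges, m))
  expect_lt(max(abs(incr - incr[1])), 1e-9)
  expect_true(all(fb$centers > fb$edges[-9] & fb$centers < fb$edges[-1]))
  for (mode in c("geometric", "arithmetic")) {
    fbm <- design_filterbank(vocoder_config(center_mode = mode), m)
    expect_true(all(fbm$centers > fbm$edges[-9] & fbm$centers < fbm$edges[-1]))
  }
  expect_error(vocoder_config(f_lo = 5000, f_hi = 100), "f_lo")
})

test_that("bandpass keeps in-band tones and attenuates out-of-band tones", {
  fb <- design_filterbank(vocoder_config())
  x_in <- tone(fb$centers[4], dur_s = 0.5)
  y_in <- bandpass(x_in, fb$edges[4], fb$edges[5])
  sel <- 2000:9000  # steady-state region
  gain_db <- 20 * log10(rms(y_in$samples[sel]) / rms(x_in$samples[sel]))
  expect_lt(abs(gain_db), 1)

  x_out <- tone(fb$edges[4] / 2, dur_s = 0.5)  # one octave below the band
  y_out <- bandpass(x_out, fb$edges[4], fb$edges[5])
  att_db <- 20 * log10(rms(y_out$samples[sel]) / rms(x_out$samples[sel]))
  expect_lt(att_db, -40)

  z <- bandpass(audio_signal(numeric(1000), 22050), 300, 600)
  expect_equal(z$samples, numeric(1000))
  expect_identical(length(y_in), length(x_in))
  expect_error(bandpass(x_in, 300, 12000), "Nyquist")
})

test_that("envelope extraction recovers the rectified-sine DC and the modulator", {
  s <- tone(1000, dur_s = 1)
  env <- extract_envelope(s)
  expect_equal(mean(env$samples[2001:20000]), 1 / pi, tolerance = 0.02)
  expect_identical(length(env), length(s))

  z <- extract_envelope(audio_signal(numeric(500), 22050))
  expect_equal(z$samples, numeric(500))

  t <- seq(0, 1 - 1 / 22050, by = 1 / 22050)
  mod <- 0.5 * (1 + sin(2 * pi * 20 * t))
  am <- audio_signal(mod * sin(2 * pi * 2000 * t), 22050)
  env_am <- extract_envelope(am)
  sel <- 2000:20000
  expect_gt(stats::cor(env_am$samples[sel], mod[sel]), 0.95)
})

test_that("vocoding conserves duration and concentrates energy at the carriers", {
  cfg <- vocoder_config()
  fb <- design_filterbank(cfg)

  silence <- audio_signal(numeric(2000), 22050)
  expect_equal(vocode(silence, cfg)$samples, numeric(2000))

  x3 <- tone(fb$centers[3], dur_s = 1)
  v3 <- vocode(x3, cfg)
  r <- carrier_rms(v3, cfg)
  expect_gte(r[3], 10 * max(r[-3]))

  set.seed(11)
  noise <- audio_signal(rnorm(22050), 22050)
  v <- vocode(noise, cfg)
  expect_identical(length(v), length(noise))
  r <- carrier_rms(v, cfg)
  mid <- sqrt(fb$centers[-8] * fb$centers[-1])  # between-carrier reference bands
  bg <- vapply(mid, function(fm) {
    n <- length(v$samples)
    spec <- abs(stats::fft(v$samples))[seq_len(n %/% 2)]
    freqs <- (seq_len(n %/% 2) - 1) * v$rate / n
    sel <- freqs >= fm * 0.96 & freqs <= fm * 1.04
    sqrt(sum(spec[sel]^2) / n^2)
  }, numeric(1))
  expect_true(all(r > 2 * max(bg)))  # 8 distinct carrier peaks

  # carrier set is preserved under re-vocoding
  v2 <- vocode(v, cfg)
  r2 <- carrier_rms(v2, cfg)
  expect_true(all(r2 > 2 * max(bg) * max(r2) / max(r)))
})

test_that("vocode rejects unusable inputs explicitly", {
  cfg <- vocoder_config()
  expect_error(vocode(audio_signal(rnorm(10), 22050), cfg), "too short")
  expect_error(vocode(audio_signal(rnorm(5000), 16000), cfg), "resample")
})
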
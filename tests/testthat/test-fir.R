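# Canonical HRF, response window, FIR design construction, GLM fitting.

test_that("canonical HRF has double-gamma shape", {
  spec <- hrf_spec()
  h <- canonical_hrf(spec)
  expect_equal(h[1L], 0)                       # value at t = 0
  expect_equal(max(h), 1)                      # peak-normalized
  # argmax against a fine-grid evaluation of the double-gamma difference
  fine <- seq(0, 30, by = 0.1)
  oracle <- stats::dgamma(fine, shape = 6, scale = 1) -
    stats::dgamma(fine, shape = 16, scale = 1) / 6
  t_peak_fine <- fine[which.max(oracle)]
  t_grid <- seq(0, 32, by = spec$tr)
  expect_lte(abs(t_grid[which.max(h)] - t_peak_fine), spec$tr / 2)
  # exactly one sign change, positive to negative (undershoot)
  s <- sign(h[h != 0])
  expect_equal(sum(diff(s) != 0), 1L)
  expect_equal(s[1L], 1)
  expect_equal(s[length(s)], -1)
  expect_error(canonical_hrf(spec, length = 0.5), "at least one TR")
  expect_error(hrf_spec(peak_delay = -1), "positive")
})

test_that("response window matches the boxcar-convolution rule", {
  w <- response_window(3)
  expect_equal(as.integer(w), 15L)
  expect_equal(attr(w, "first_negative_s"), 14)
  # direct-summation oracle for the convolution
  h <- canonical_hrf()
  conv <- vapply(seq_along(h), function(i)
    sum(h[max(1L, i - 2L):i]), numeric(1))
  expect_equal(which(conv < 0)[1L] - 1L, 14L)
  expect_lte(response_window(0.5), w)          # impulse smears less
  expect_gte(response_window(6), 15L)
  expect_error(response_window(0), "positive")
})

test_that("design bookkeeping matches the blocked two-day structure", {
  p <- tiny_params()
  st <- tiny_study()
  sched1 <- st$schedule[st$schedule$participant == 1L, ]
  d_inc <- build_fir_design(sched1, hard_incorrect_condition(), 15L,
                            frames_per_run = p$frames_per_run)
  expect_equal(ncol(d_inc$matrix), 32L)        # 15 FIR + day + 16 scans
  d_diff <- build_fir_design(sched1, difficulty_conditions(), 15L,
                             frames_per_run = p$frames_per_run)
  expect_equal(length(d_diff$fir_columns), 45L)
  expect_equal(ncol(d_diff$matrix), 45L + 1L + 16L)
  expect_true(all(d_diff$matrix[, d_diff$fir_columns] %in% c(0, 1)))
  # a condition with at least one trial has no all-zero FIR column
  expect_true(all(colSums(d_diff$matrix[, d_diff$fir_columns]) > 0))
  expect_error(build_fir_design(sched1[0, ], difficulty_conditions(), 15L,
                                frames_per_run = 50L), "empty")
  expect_error(build_fir_design(sched1, difficulty_conditions(), 15L,
                                frames_per_run = 50L,
                                onset_rounding = "strict"), "grid")
})

# A grid-aligned world with window-limited kernel and spaced trials, where
# least squares must recover the injected response exactly.
exact_world <- function(noise_runs = NULL) {
  roles <- data.frame(region = 1:3, sign = c(1L, -1L, 0L),
                      gain = c(0.5, 0.5, 0), delayed = FALSE)
  p <- generator_params(n_participants = 1L, n_regions = 3L, roles = roles,
                        noise_sd = 0, frames_per_run = 80L, seed = 13L)
  sched <- do.call(rbind, lapply(1:2, function(r) data.frame(
    participant = 1L, day = 1L + (r > 1L), scan = 1L, trial_index = 1:3,
    onset = c(5, 25, 45), duration = 3, difficulty = 0:2, correct = TRUE,
    rt = 1)))
  class(sched) <- c("trial_table", "data.frame")
  h15 <- canonical_hrf()[1:15]
  bold <- generate_bold(sched, p, hrf = h15)
  list(p = p, sched = sched, bold = bold, h15 = h15)
}

test_that("noiseless FIR betas equal the injected response shape", {
  w <- exact_world()
  des <- build_fir_design(w$sched, difficulty_conditions(), 15L,
                          frames_per_run = 80L, onset_rounding = "strict")
  fit <- fit_fir(w$bold, des)
  for (lev in 0:2) {
    cn <- c("easy_correct", "medium_correct", "hard_correct")[lev + 1L]
    amp <- 1 + 0.5 * lev
    expect_equal(unname(fit$betas[[cn]][1L, ]), amp * w$h15, tolerance = 1e-8)
    expect_equal(unname(fit$betas[[cn]][2L, ]), -amp * w$h15, tolerance = 1e-8)
    expect_equal(unname(fit$betas[[cn]][3L, ]), rep(0, 15L), tolerance = 1e-8)
  }
})

test_that("least-squares linearity and zero-data behavior", {
  w <- exact_world()
  des <- build_fir_design(w$sched, difficulty_conditions(), 15L,
                          frames_per_run = 80L)
  Y <- do.call(cbind, lapply(w$bold, function(b) b$data))
  fit0 <- fit_fir(matrix(0, 3L, ncol(Y)), des)
  expect_true(all(unlist(fit0$betas) == 0))
  # betas(a Y1 + b Y2) = a betas(Y1) + b betas(Y2)
  set.seed(42)
  Y2 <- matrix(rnorm(length(Y)), nrow(Y))
  fa <- fit_fir(2 * Y + 3 * Y2, des)
  f1 <- fit_fir(Y, des); f2 <- fit_fir(Y2, des)
  expect_equal(fa$betas$hard_correct,
               2 * f1$betas$hard_correct + 3 * f2$betas$hard_correct,
               tolerance = 1e-8)
  # opposite-sign noise in two identical runs cancels
  noise <- matrix(rnorm(3L * 80L), 3L)
  Yn <- Y; Yn[, 1:80] <- Yn[, 1:80] + noise
  Yn[, 81:160] <- Yn[, 81:160] - noise
  expect_equal(fit_fir(Yn, des)$betas$hard_correct, f1$betas$hard_correct,
               tolerance = 1e-8)
  expect_error(fit_fir(Y[, -1], des), "do not match")
  Yna <- Y; Yna[1L, 1L] <- NA
  expect_error(fit_fir(Yna, des), "NA")
})

test_that("mixed and fixed fits agree on balanced noiseless data", {
  w <- exact_world()
  des <- build_fir_design(w$sched, difficulty_conditions(), 15L,
                          frames_per_run = 80L)
  f_fixed <- fit_fir(w$bold, des, method = "fixed")
  f_mixed <- suppressWarnings(fit_fir(w$bold, des, method = "mixed"))
  expect_equal(f_mixed$betas$hard_correct, f_fixed$betas$hard_correct,
               tolerance = 1e-6)
})

test_that("joint study fit unmixes overlapping conditions", {
  fb <- tiny_betas()
  p <- tiny_params()
  h <- canonical_hrf()
  # gain regions: hard-correct amplitude = 2x easy amplitude, in-window part
  hc <- colMeans(fb[, "hard_correct", 1:8, ], dims = 2)
  ec <- colMeans(fb[, "easy_correct", 1:8, ], dims = 2)
  expect_gt(stats::cor(hc, h[1:15]), 0.95)
  expect_gt(mean(hc[4:8]) / mean(ec[4:8]), 1.5)
  # unresponsive regions stay near baseline
  expect_lt(max(abs(colMeans(fb[, "hard_correct", 20:40, ], dims = 2))), 0.2)
})
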
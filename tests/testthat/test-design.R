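test_that("winsorize-then-centre: hand computation, bounds, zero mean", {
  v <- c(rep(0, 9), 100)
  m <- mean(v); s <- sd(v)            # 10, sqrt(1000)
  hi <- m + 2 * s
  clipped <- pmin(v, hi)
  expected <- clipped - mean(clipped)
  mod <- prepare_modulator(v)
  expect_equal(mod$value, expected)
  expect_equal(attr(mod, "n_winsorized"), 1L)
  expect_lt(abs(mean(mod$value)), 1e-12)
  expect_true(all(mod$value <= hi))

  # already zero-mean values within bounds are untouched
  u <- c(-1, 0, 1, 0.5, -0.5)
  expect_equal(prepare_modulator(u)$value, u)
})

test_that("preparation is idempotent and per-run", {
  set.seed(7)
  raw <- c(rnorm(10, 50, 8), rnorm(10, 30, 5))
  runs <- rep(1:2, each = 10)
  mod <- prepare_modulator(raw, run_ids = runs)
  for (r in 1:2) {
    expect_lt(abs(mean(mod$value[mod$run_id == r])), 1e-10)
  }
  # re-preparing the prepared object is a no-op by contract
  expect_message(again <- prepare_modulator(mod), "already prepared")
  expect_identical(again, mod)
  # and re-running the numeric recipe on realistic values is a fixed point
  twice <- prepare_modulator(mod$value, run_ids = runs)
  expect_equal(twice$value, mod$value)
  # zero-variance run: centering only, warned
  expect_warning(z <- prepare_modulator(c(5, 5, 5, 1, 2, 3),
                                        run_ids = rep(1:2, each = 3)),
                 "zero variance")
  expect_equal(z$value[1:3], c(0, 0, 0))
})

test_that("early/late shifts reassign block values within trials", {
  # 10-block trial with distinct values
  mod <- prepare_modulator(c(31:40, 11:20), run_ids = 1,
                           trial_ids = rep(1:2, each = 10))
  early <- shift_modulator(mod, -1)
  late <- suppressMessages(shift_modulator(mod, +1))
  # the value block 4 carried appears at block 3 (early) and block 5 (late)
  t1 <- mod$trial_id == 1
  expect_equal(early$value[t1][3], mod$value[t1][4])
  expect_equal(late$value[t1][5], mod$value[t1][4])
  # brute-force reindexing oracle over the full trial
  for (tr in 1:2) {
    sel <- mod$trial_id == tr
    v <- mod$value[sel]
    expect_equal(early$value[sel], c(v[2:10], v[10]))
    expect_equal(late$value[sel], c(v[1], v[1:9]))
  }
  # early-then-late differs from the original only at trial-edge blocks
  back <- suppressMessages(shift_modulator(early, +1))
  diffs <- which(abs(back$value - mod$value) > 1e-12)
  edge_blocks <- mod$block[diffs]
  expect_true(all(edge_blocks %in% c(1L, 10L)))
  expect_error(shift_modulator(mod, 10), ">=")
  expect_error(shift_modulator(mod, 0), "nonzero")
})

test_that("time-in-trial covariate is the block index, centred sums to zero", {
  tt <- time_in_trial_covariate(50, 5)
  expect_identical(tt, 1:10)
  prep <- prepare_modulator(tt)
  expect_lt(abs(sum(prep$value)), 1e-10)
  # perfectly anti-correlated with a linear coherence decay by construction
  decay <- seq(80, 35, length.out = 10)
  expect_equal(cor(tt, decay), -1)
})

test_that("canonical HRF shape: peak 5-6 s, undershoot, 32-s support", {
  t <- seq(0, 40, by = 0.1)
  h <- canonical_hrf(t)
  expect_equal(t[which.max(h)], 5, tolerance = 0.2)
  expect_lt(min(h[t > 10 & t < 20]), 0)      # undershoot
  expect_true(all(h[t > 32] == 0))
  expect_true(all(h[t < 0] == 0))
})

test_that("HRF convolution: impulse response, linearity, boxcar oracle", {
  tr <- 2.2; mtr <- 16L
  n_vol <- 40L
  dt <- tr / mtr
  imp <- numeric(n_vol * mtr); imp[1] <- 1
  got <- hrf_convolve(imp, tr, mtr)
  # impulse response equals the (unit-sum) HRF sampled at volume times
  h <- canonical_hrf(seq(0, 32, by = dt)); h <- h / sum(h)
  sample_t <- ((seq_len(n_vol) - 1L) * mtr + 9L - 1L) * dt
  expect_equal(got, approx(seq(0, 32, by = dt), h, xout = sample_t,
                           yleft = 0, yright = 0)$y, tolerance = 1e-12)
  peak_s <- sample_t[which.max(got)]
  expect_true(peak_s > 4 && peak_s < 7)

  # linearity: two disjoint boxcars
  b1 <- numeric(n_vol * mtr); b1[17:48] <- 1
  b2 <- numeric(n_vol * mtr); b2[301:380] <- 0.7
  expect_equal(hrf_convolve(b1 + b2, tr, mtr),
               hrf_convolve(b1, tr, mtr) + hrf_convolve(b2, tr, mtr),
               tolerance = 1e-10)

  # 5-s boxcar vs direct discrete-convolution oracle
  box <- numeric(n_vol * mtr)
  on <- seq_along(box) * dt
  box[on > 10 & on <= 15] <- 1
  direct <- sapply(seq_len(n_vol), function(v) {
    ts <- ((v - 1L) * mtr + 8L) * dt
    lag <- ts - (seq_along(box) - 1L) * dt
    sum(box * canonical_hrf(lag)) / sum(canonical_hrf(seq(0, 32, by = dt)))
  })
  expect_equal(hrf_convolve(box, tr, mtr), direct, tolerance = 1e-8)
})

test_that("DCT drift basis column count follows the high-pass rule", {
  # 960-s run: floor(2 * 960 / 180) = 10 columns
  tr <- 2
  b <- dct_drift_basis(480, tr, cutoff = 180)
  expect_equal(ncol(b), 10L)
  # cutoff longer than twice the run -> no drift columns
  expect_equal(ncol(dct_drift_basis(30, 2, cutoff = 180)), 0L)
  # DCT columns are orthogonal
  expect_equal(crossprod(b) / diag(crossprod(b))[1], diag(10),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("build_design assembles condition, modulator, nuisance, drift and intercept columns", {
  timings <- trial_timing(
    condition = rep(c("extended_planning", "extended_production",
                      "automatic_planning", "automatic_production"), 2),
    onset = c(0, 8, 70, 78, 100, 108, 170, 178),
    duration = rep(c(8, 50, 8, 15), 2),
    run = rep(1:2, each = 4))
  coh <- prepare_modulator(seq(40, 58, by = 2), run_ids = 1)
  tim <- prepare_modulator(1:10, run_ids = 1)
  n_vol <- 90
  nuis <- matrix(rnorm(2 * n_vol * 3), ncol = 3,
                 dimnames = list(NULL, paste0("motion", 1:3)))
  des <- build_design(timings,
                      modulators = list(coherence = rbind(coh, coh),
                                        time = rbind(tim, tim)),
                      nuisance = nuis, n_volumes = n_vol, tr = 2.2)
  expect_equal(nrow(des$matrix), 180)
  expect_true(all(c("extended_planning", "extended_production",
                    "automatic_planning", "automatic_production",
                    "coherence", "time", "motion1",
                    "run1_intercept", "run2_intercept") %in% des$names))
  # drift: 90 volumes x 2.2 s = 198 s -> floor(2*198/180) = 2 per run
  expect_equal(sum(grepl("dct", des$names)), 4L)
  # no all-zero task regressor
  expect_true(all(colSums(abs(des$matrix[, des$task_columns])) > 0))
  # bit-identical reproducibility
  des2 <- build_design(timings,
                       modulators = list(coherence = rbind(coh, coh),
                                         time = rbind(tim, tim)),
                       nuisance = nuis, n_volumes = n_vol, tr = 2.2)
  expect_identical(des$matrix, des2$matrix)
  # modulator length mismatch is a schema error
  expect_error(build_design(timings, modulators = list(coherence = coh),
                            n_volumes = n_vol, tr = 2.2),
               "production blocks")
})

test_that("design without events carries only nuisance/drift/intercept columns", {
  timings <- trial_timing(character(0), numeric(0), numeric(0),
                          run = integer(0))
  nuis <- matrix(1:40, ncol = 1, dimnames = list(NULL, "noise1"))
  expect_error(build_design(timings, nuisance = nuis, n_volumes = 40,
                            tr = 2.2), NA)
})

test_that("events past scan end are truncated with a warning", {
  timings <- trial_timing("extended_production", onset = 80, duration = 50)
  expect_warning(build_design(timings, n_volumes = 50, tr = 2.2),
                 "truncated")
})
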
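make_design <- function(n_vol = 60, tr = 2.2, seed = 1) {
  timings <- trial_timing(
    condition = c("extended_planning", "extended_production",
                  "automatic_planning", "automatic_production"),
    onset = c(0, 8, 70, 78), duration = c(8, 50, 8, 15))
  set.seed(seed)
  coh <- prepare_modulator(rnorm(10, 50, 10))
  build_design(timings, modulators = list(coherence = coh),
               n_volumes = n_vol, tr = tr)
}

test_that("noiseless data reproduce the planted betas exactly", {
  des <- make_design()
  spec <- bold_sim_spec(dims = c(5, 5, 5), noise_sd = 0, seed = 2)
  sim <- generate_bold(des, spec,
                       betas = list(extended_production = 2,
                                    coherence = 0.5))
  fit <- fit_glm(sim$bold, des)
  expect_equal(max(abs(fit$beta["extended_production", ] - 2)), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(fit$beta["coherence", ] - 0.5)), 0,
               tolerance = 1e-8)
  expect_equal(fit$df, nrow(des$matrix) - qr(des$matrix)$rank)
})

test_that("pure-noise data yield near-zero mean t", {
  des <- make_design()
  spec <- bold_sim_spec(dims = c(8, 8, 8), noise_sd = 1, ar1 = 0,
                        seed = 33)
  sim <- generate_bold(des, spec)
  fit <- fit_glm(sim$bold, des)
  con <- contrast(fit, c(coherence = 1))
  se_mean <- sd(con$t) / sqrt(length(con$t))
  expect_lt(abs(mean(con$t)), 3 * se_mean + 0.02)
})

test_that("adding a constant moves only the intercept beta", {
  des <- make_design()
  Y <- matrix(rnorm(nrow(des$matrix) * 4), ncol = 4)
  f1 <- fit_glm(Y, des)
  f2 <- fit_glm(Y + 7, des)
  ic <- grep("intercept", rownames(f1$beta))
  expect_equal(f1$beta[-ic, ], f2$beta[-ic, ], tolerance = 1e-10)
  expect_equal(unname(f2$beta[ic, ] - f1$beta[ic, ]), rep(7, 4),
               tolerance = 1e-8)
})

test_that("contrasts: zero weights, planted effect, sign flip, t = effect/se", {
  des <- make_design()
  spec <- bold_sim_spec(dims = c(4, 4, 4), noise_sd = 0.05, ar1 = 0,
                        seed = 4)
  sim <- generate_bold(des, spec, betas = list(coherence = 2.0))
  fit <- fit_glm(sim$bold, des)
  z <- contrast(fit, rep(0, nrow(fit$beta)))
  expect_true(all(z$effect == 0))
  cp <- contrast(fit, c(coherence = 1))
  expect_equal(mean(cp$effect), 2.0, tolerance = 0.05)
  cn <- contrast(fit, c(coherence = -1))
  expect_equal(cn$effect, -cp$effect)
  expect_equal(cn$t, -cp$t)
  ok <- cp$se > 0
  expect_equal(cp$t[ok], cp$effect[ok] / cp$se[ok])
  expect_error(contrast(fit, c(bogus = 1)), "unknown regressor")
})

test_that("rank-deficient designs are flagged with the dependent column named", {
  X <- cbind(a = rep(1, 20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_warning(fit <- fit_glm(matrix(rnorm(20)), X), "c")
  expect_equal(fit$df, 20 - 2)
})

test_that("mean scan-to-scan displacement summarises motion", {
  mp <- matrix(0, 50, 6)
  expect_equal(mean_displacement(mp), 0)
  mp2 <- mp; mp2[, 3] <- seq_len(50)   # steps of 1 in one parameter
  expect_equal(mean_displacement(mp2), 1 / 6)
  set.seed(5)
  mp3 <- matrix(rnorm(300), 50, 6)
  expect_equal(mean_displacement(2 * mp3), 2 * mean_displacement(mp3))
  # oracle: direct formula
  expect_equal(mean_displacement(mp3),
               mean(apply(mp3, 2, function(p) mean(abs(diff(p))))))
})

test_that("second level: covariate recovery, degenerate variance, centering", {
  set.seed(6)
  n <- 16
  cov <- rnorm(n, 0, 1)
  maps <- matrix(1.5 + 0.8 * cov + rnorm(n, sd = 0.3), ncol = 1)
  res <- second_level(maps, covariates = cbind(displacement = cov))
  expect_gt(res$t["displacement", 1], 2)
  expect_gt(res$effect["intercept", 1], 0)
  # identical maps: zero variance -> flagged infinite one-sample t
  same <- matrix(rep(3, 6), ncol = 1)
  res2 <- second_level(same)
  expect_true(is.infinite(res2$t["intercept", 1]) &&
                res2$t["intercept", 1] > 0)
  # covariate orthogonal to the intercept by construction leaves the
  # one-sample effect estimate unchanged
  ortho <- scale(rnorm(n), scale = FALSE)
  res3 <- second_level(maps, covariates = cbind(c1 = as.numeric(ortho)))
  res0 <- second_level(maps)
  expect_equal(res3$effect["intercept", 1], res0$effect["intercept", 1],
               tolerance = 1e-10)
  expect_error(second_level(maps[1:2, , drop = FALSE]), "3 participants")
  expect_error(second_level(maps, covariates = cbind(a = cov, b = cov)),
               "collinear")
})

test_that("statistic maps rebuild onto the mask grid", {
  des <- make_design()
  mask <- array(FALSE, c(4, 4, 4)); mask[2:3, 2:3, 2:3] <- TRUE
  arr <- array(rnorm(4 * 4 * 4 * nrow(des$matrix)),
               c(4, 4, 4, nrow(des$matrix)))
  bd <- bold_dataset(arr, mask = mask, tr = 2.2)
  fit <- fit_glm(bd, des)
  expect_equal(ncol(fit$beta), 8L)
  con <- contrast(fit, c(coherence = 1))
  m <- as_map(con, "t")
  expect_identical(dim(m), dim(mask))
  expect_true(all(is.na(m[!mask])))
  expect_equal(sum(!is.na(m)), 8L)
})
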
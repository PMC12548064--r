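make_assoc_fixture <- function(n = 180L, seed = 8L, plate_sd = 0.15,
                               delta = 0.3) {
  spec <- cohort_spec(n_natural = n, n_art = n %/% 2L,
                      twin_pair_count_art = 0L, plate_sd = plate_sd,
                      seed = seed)
  sheet <- generate_cohort(spec)
  man <- one_probe_manifest()
  eff <- effect_profile(man$probe_id, delta_birth = delta)
  mat <- generate_methylation(sheet, man, eff, spec)
  birth <- sheet[sheet$timepoint == "birth", ]
  enc <- encode_covariates(birth, "birth")
  list(y = mat$values[1, birth$sample_id], enc = enc, birth = birth,
       sheet = sheet, mat = mat, man = man)
}

test_that("zero plate variance reduces the mixed model to OLS", {
  fx <- make_assoc_fixture(plate_sd = 0, seed = 14L)
  keep <- fx$enc$complete
  res <- fit_cpg_lmm(fx$y[keep], fx$enc$design[keep, ], fx$birth$plate_id[keep])
  dat <- data.frame(y = fx$y[keep], fx$enc$design[keep, ])
  ols <- lm(y ~ ., data = dat)
  expect_true(res$converged)
  expect_lt(abs(res$beta_hat - coef(ols)[["art"]]), 1e-6)
  expect_equal(res$ci_low, res$beta_hat - 1.96 * res$se)
  expect_equal(res$ci_high, res$beta_hat + 1.96 * res$se)
  expect_equal(res$n_used, sum(keep))
})

test_that("mixed fit equals the closed-form GLS oracle at its own variance components", {
  # small balanced design with a strong plate effect so the variance
  # estimate is interior (not at the boundary)
  set.seed(33)
  n <- 12L
  plate <- rep(c("a", "b", "c"), each = 4L)
  art <- rep(c(0, 1), 6L)
  age <- rnorm(n, 31, 3)
  y <- 1 + 0.5 * art + 0.02 * age +
    rep(rnorm(3, 0, 2), each = 4L) + rnorm(n, 0, 0.3)
  design <- cbind(art = art, maternal_age = age)
  res <- fit_cpg_lmm(y, design, plate)
  expect_true(res$converged)
  expect_gt(res$plate_variance, 0)

  # GLS with V = sigma_plate^2 ZZ' + sigma_e^2 I at the REML estimates
  dat <- data.frame(y = y, art = art, maternal_age = age, plate = plate)
  fit <- lme4::lmer(y ~ art + maternal_age + (1 | plate), data = dat)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_plate <- vc$vcov[vc$grp == "plate"]
  s2_e <- vc$vcov[vc$grp == "Residual"]
  Z <- model.matrix(~ 0 + factor(plate))
  V <- s2_plate * Z %*% t(Z) + s2_e * diag(n)
  X <- cbind(1, design)
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, y))
  expect_lt(abs(res$beta_hat - beta_gls["art", 1]), 1e-8)
})

test_that("BH adjustment matches the explicit min-over-ranks oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "first")
    vapply(seq_len(m), function(i) {
      min(1, min((p * m / r)[r >= r[i]]))
    }, numeric(1))
  }
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(rep(0.5, 10)), rep(0.5, 10))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone nondecreasing in the sorted order of raw p
  p <- runif(40)
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= -1e-15))
})

test_that("run_association is deterministic and recovers injected effects", {
  fx <- make_assoc_fixture(n = 300L, seed = 25L, delta = 0.4)
  ded <- dedup_twins(fx$sheet, 1L)
  r1 <- run_association(fx$mat, ded, fx$man, "birth")
  r2 <- run_association(fx$mat, ded, fx$man, "birth")
  expect_identical(r1, r2)
  expect_equal(r1$timepoint, "birth")
  expect_true(r1$p_fdr >= r1$p_raw)
  # strong injected effect is detected and estimated near truth
  expect_lt(r1$p_raw, 0.01)
  expect_lt(abs(r1$beta_hat - 0.4), 4 * r1$se)
  expect_error(run_association(fx$mat, ded,
                               data.frame(probe_id = "cgX", position = 1L),
                               "birth"),
               "no probes shared")
})

test_that("irrelevant cell-fraction covariates barely move the estimates", {
  spec <- cohort_spec(seed = 19L)
  sheet <- generate_cohort(spec)
  man <- default_manifest()[1:8, ]
  mat <- generate_methylation(sheet, man,
                              effect_profile(man$probe_id,
                                             delta_birth = 0.13), spec)
  ded <- dedup_twins(sheet, 1L)
  set.seed(44)
  f1 <- runif(nrow(ded), 0.3, 0.5)
  f2 <- runif(nrow(ded), 0.2, 0.4)
  ded$cellfrac_a <- f1
  ded$cellfrac_b <- f2
  ded$cellfrac_c <- 1 - f1 - f2
  plain <- run_association(mat, ded, man, "birth")
  adj <- run_association(mat, ded, man, "birth",
                         include_cell_fractions = TRUE)
  expect_true(all(abs(adj$beta_hat - plain$beta_hat) < 0.5 * plain$se))
})

test_that("outlier-flagged samples are excluded from the fit", {
  fx <- make_assoc_fixture(n = 200L, seed = 51L, delta = 0)
  target <- fx$birth$sample_id[5]
  spiked <- inject_outliers(fx$mat, fx$man$probe_id[1], target, 12)
  res <- run_association(spiked, fx$sheet, fx$man, "birth")
  base <- run_association(fx$mat, fx$sheet, fx$man, "birth")
  expect_equal(res$n_outliers, 1L)
  expect_equal(res$n_used, base$n_used - 1L)
})
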
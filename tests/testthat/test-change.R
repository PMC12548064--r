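make_change_fixture <- function(seed = 7L, delta_birth = 0,
                                delta_postnatal = 0, n_probes = 3L) {
  spec <- cohort_spec(seed = seed)
  sheet <- generate_cohort(spec)
  ded <- dedup_twins(sheet, seed + 1L)
  man <- default_manifest()[seq_len(n_probes), ]
  eff <- effect_profile(man$probe_id, delta_birth = delta_birth,
                        delta_postnatal = delta_postnatal)
  mat <- generate_methylation(sheet, man, eff, spec)
  mats <- split_by_timepoint(mat, ded)
  list(spec = spec, sheet = ded, man = man, mats = mats)
}

test_that("standardized residuals have mean 0 and SD 1 within 1e-10", {
  fx <- make_change_fixture(seed = 3L)
  for (tp in c("birth", "postnatal")) {
    rows <- fx$sheet[fx$sheet$timepoint == tp, ]
    y <- fx$mats[[tp]]$values[1, rows$sample_id]
    z <- residualize_standardize(y, rows, tp)
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(sd(z) - 1), 1e-10)
    expect_identical(names(z), rows$sample_id)
  }
})

test_that("a perfectly explained outcome is a degenerate-probe error", {
  rows <- generate_cohort(small_spec(seed = 2L))
  rows <- rows[rows$timepoint == "birth", ]
  y <- 2 * (rows$sex == "male")
  expect_error(residualize_standardize(y, rows, "birth"), "degenerate")
})

test_that("plate shifts are absorbed by the random intercept", {
  # plate shift dominating the noise: raw values track plate means almost
  # perfectly, standardized residuals must not
  spec <- cohort_spec(plate_sd = 1, seed = 23L)
  sheet <- dedup_twins(generate_cohort(spec), 1L)
  man <- one_probe_manifest()
  mat <- generate_methylation(sheet, man, effect_profile(noise_scale = 0.2),
                              spec)
  rows <- sheet[sheet$timepoint == "birth", ]
  y <- mat$values[1, rows$sample_id]
  z <- residualize_standardize(y, rows, "birth")
  plate_means <- tapply(y, rows$plate_id, mean)[rows$plate_id]
  expect_gt(abs(cor(y, plate_means)), 0.8)
  expect_lt(abs(cor(z, plate_means)), 0.05)
})

test_that("identical residuals at both timepoints give a null change result", {
  fx <- make_change_fixture(seed = 5L)
  sheet <- fx$sheet
  birth_rows <- sheet[sheet$timepoint == "birth", ]
  post_rows <- sheet[sheet$timepoint == "postnatal", ]
  both <- intersect(birth_rows$child_id, post_rows$child_id)
  z <- rnorm(length(both))
  z_birth <- setNames(z, birth_rows$sample_id[match(both,
                                                    birth_rows$child_id)])
  z_post <- setNames(z, post_rows$sample_id[match(both,
                                                  post_rows$child_id)])
  expect_warning(res <- within_child_change(z_birth, z_post, sheet),
                 "constant")
  expect_equal(res$beta_hat, 0)
  expect_equal(res$p_raw, 1)
})

test_that("an effect present at birth only fades in the change statistic", {
  coefs <- vapply(1:8, function(s) {
    fx <- make_change_fixture(seed = 100L + s, delta_birth = 0.13,
                              delta_postnatal = 0, n_probes = 2L)
    res <- run_change(fx$mats$birth, fx$mats$postnatal, fx$sheet, fx$man)
    mean(res$beta_hat)
  }, numeric(1))
  # postnatal - birth differencing makes a fading effect negative on average
  expect_lt(mean(coefs), 0)
})

test_that("change results are invariant to affine rescaling of one timepoint", {
  fx <- make_change_fixture(seed = 9L)
  base <- run_change(fx$mats$birth, fx$mats$postnatal, fx$sheet, fx$man)
  rescaled <- methyl_matrix(3.2 + 1.7 * fx$mats$birth$values, "M")
  alt <- run_change(rescaled, fx$mats$postnatal, fx$sheet, fx$man)
  expect_equal(alt$beta_hat, base$beta_hat, tolerance = 1e-8)
  expect_equal(alt$p_raw, base$p_raw, tolerance = 1e-8)
})

test_that("the change direction flag flips the sign convention", {
  fx <- make_change_fixture(seed = 13L)
  fwd <- run_change(fx$mats$birth, fx$mats$postnatal, fx$sheet, fx$man)
  rev <- run_change(fx$mats$birth, fx$mats$postnatal, fx$sheet, fx$man,
                    direction = "birth_minus_postnatal")
  expect_equal(rev$beta_hat, -fwd$beta_hat, tolerance = 1e-10)
  expect_equal(rev$p_raw, fwd$p_raw, tolerance = 1e-10)
})

test_that("only children with both timepoints enter the change model", {
  fx <- make_change_fixture(seed = 15L)
  res <- run_change(fx$mats$birth, fx$mats$postnatal, fx$sheet, fx$man)
  n_birth <- sum(fx$sheet$timepoint == "birth")
  n_post <- sum(fx$sheet$timepoint == "postnatal")
  expect_true(all(res$n_children <= min(n_birth, n_post)))
  both <- length(intersect(
    fx$sheet$child_id[fx$sheet$timepoint == "birth"],
    fx$sheet$child_id[fx$sheet$timepoint == "postnatal"]))
  expect_true(all(res$n_children <= both))

  # too few complete pairs is an explicit error
  rows_b <- fx$sheet[fx$sheet$timepoint == "birth", ]
  rows_p <- fx$sheet[fx$sheet$timepoint == "postnatal", ]
  zb <- residualize_standardize(fx$mats$birth$values[1, rows_b$sample_id],
                                rows_b, "birth")
  zp <- residualize_standardize(
    fx$mats$postnatal$values[1, rows_p$sample_id], rows_p, "postnatal")
  expect_error(within_child_change(zb[1:5], zp, fx$sheet), "children")
})

test_that("permuting conception labels centres the change coefficient at 0", {
  fx <- make_change_fixture(seed = 29L, delta_birth = 0.13)
  sheet <- fx$sheet
  rows_b <- sheet[sheet$timepoint == "birth", ]
  rows_p <- sheet[sheet$timepoint == "postnatal", ]
  zb <- residualize_standardize(fx$mats$birth$values[1, rows_b$sample_id],
                                rows_b, "birth")
  zp <- residualize_standardize(
    fx$mats$postnatal$values[1, rows_p$sample_id], rows_p, "postnatal")
  set.seed(77)
  perm_coefs <- vapply(1:100, function(i) {
    sh <- sheet
    child <- unique(sh$child_id)
    relabel <- setNames(sample(sh$conception[!duplicated(sh$child_id)]),
                        child)
    sh$conception <- unname(relabel[sh$child_id])
    within_child_change(zb, zp, sh)$beta_hat
  }, numeric(1))
  expect_lt(abs(mean(perm_coefs)), 3 * sd(perm_coefs) / sqrt(100))
})
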
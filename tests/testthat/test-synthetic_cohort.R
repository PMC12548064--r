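test_that("cohort generation is reproducible and honors the twin setting", {
  spec <- small_spec(seed = 9L)
  s1 <- generate_cohort(spec)
  s2 <- generate_cohort(spec)
  expect_identical(s1, s2)

  no_twins <- cohort_spec(n_natural = 40L, n_art = 20L,
                          twin_pair_count_art = 0L, seed = 2L)
  sheet <- generate_cohort(no_twins)
  expect_true(all(is.na(sheet$twin_pair_id)))

  # spec validation names the offending covariate
  bad <- default_marginals()
  bad$smoking$natural <- c(No = 0.5, Sometimes = 0.4, Daily = 0.2)
  expect_error(cohort_spec(covariate_marginals = bad), "smoking")
})

test_that("two-timepoint availability matches the cohort rate", {
  frac <- vapply(1:10, function(s) {
    sheet <- generate_cohort(cohort_spec(seed = s))
    art <- sheet[sheet$conception == "ART", ]
    both <- tapply(art$timepoint, art$child_id,
                   function(x) length(unique(x)) == 2L)
    mean(both)
  }, numeric(1))
  # 10 x 119 ART children, binomial SE ~ 0.0123
  expect_lt(abs(mean(frac) - 80 / 105), 3 * sqrt((80 / 105) * (25 / 105) /
                                                   (10 * 119)))
})

test_that("covariate marginals of a large cohort match the spec within 3 SE", {
  spec <- cohort_spec(n_natural = 6000L, n_art = 4000L,
                      twin_pair_count_art = 0L, seed = 31L)
  sheet <- generate_cohort(spec)
  child <- sheet[!duplicated(sheet$child_id), ]
  nat <- child[child$conception == "natural", ]
  art <- child[child$conception == "ART", ]

  check <- function(obs_p, true_p, n) {
    expect_lt(abs(obs_p - true_p), 3 * sqrt(true_p * (1 - true_p) / n))
  }
  check(mean(nat$smoking == "No"), 191 / 250, nrow(nat))
  check(mean(art$smoking == "No"), 91 / 105, nrow(art))
  check(mean(nat$sex == "male"), 102 / 250, nrow(nat))
  check(mean(is.na(nat$bmi_category)), 14 / 250, nrow(nat))
  check(mean(art$parity == 0), 71 / 105, nrow(art))
  check(mean(art$multiple_birth), 24 / 105, nrow(art))
  # truncated-normal maternal age: means within 3 SE of the group targets
  expect_lt(abs(mean(nat$maternal_age) - 31.3), 3 * 4.5 / sqrt(nrow(nat)) + 0.1)
  expect_lt(abs(mean(art$maternal_age) - 33.8), 3 * 4.5 / sqrt(nrow(art)) + 0.1)
  expect_true(all(child$maternal_age >= 17 & child$maternal_age <= 45))
  post <- sheet[sheet$timepoint == "postnatal", ]
  expect_true(all(post$child_age >= 3 & post$child_age <= 22))
})

test_that("methylation simulator reproduces its generative moments", {
  man <- default_manifest()
  spec <- cohort_spec(n_natural = 1500L, n_art = 1500L,
                      twin_pair_count_art = 0L,
                      p_two_timepoints_natural = 0,
                      p_two_timepoints_art = 0,
                      p_birth_only_single_natural = 1,
                      p_birth_only_single_art = 1,
                      plate_sd = 0, seed = 17L)
  sheet <- generate_cohort(spec)

  # noise-free limit: constant at the intercept
  quiet <- effect_profile(noise_scale = 1e-9, noise_df = 10)
  m0 <- generate_methylation(sheet, man[1:2, ], quiet, spec)
  expect_lt(max(abs(m0$values - 1.2)), 1e-6)

  # injected birth effect of 0.13 recovered as a group-mean difference
  eff <- effect_profile(man$probe_id[1], delta_birth = 0.13)
  m1 <- generate_methylation(sheet, man[1:2, ], eff, spec)
  art_ids <- sheet$sample_id[sheet$conception == "ART"]
  nat_ids <- sheet$sample_id[sheet$conception == "natural"]
  diff1 <- mean(m1$values[1, art_ids]) - mean(m1$values[1, nat_ids])
  sd_noise <- 0.49 * sqrt(10 / 8)
  expect_lt(abs(diff1 - 0.13), 3 * sd_noise * sqrt(2 / 1500))
  # unprofiled probe carries no effect
  diff2 <- mean(m1$values[2, art_ids]) - mean(m1$values[2, nat_ids])
  expect_lt(abs(diff2), 3 * sd_noise * sqrt(2 / 1500))

  # t(10) noise scaled by 0.49 has SD 0.49 * sqrt(10/8) ~ 0.548
  null_eff <- effect_profile()
  m2 <- generate_methylation(sheet, man[1:5, ], null_eff, spec)
  expect_lt(abs(sd(as.vector(m2$values)) - sd_noise), 0.01)

  # determinism under the seed
  expect_identical(generate_methylation(sheet, man[1:5, ], null_eff, spec),
                   m2)

  # probes missing from the manifest are reported by ID
  orphan <- effect_profile("cg_does_not_exist", delta_birth = 1)
  expect_error(generate_methylation(sheet, man, orphan, spec),
               "cg_does_not_exist")
})

test_that("outlier injection shifts targeted cells in MAD units", {
  spec <- small_spec(seed = 12L)
  sheet <- generate_cohort(spec)
  man <- default_manifest()
  mat <- generate_methylation(sheet, man, effect_profile(), spec)
  pid <- man$probe_id[3]
  target <- sheet$sample_id[sheet$timepoint == "birth"][1]

  v <- mat$values[pid, ]
  med <- median(v); madv <- median(abs(v - med))

  recentred <- inject_outliers(mat, pid, target, 0)
  expect_equal(unname(recentred$values[pid, target]), med)
  untouched <- setdiff(colnames(mat$values), target)
  expect_identical(recentred$values[, untouched], mat$values[, untouched])

  far <- inject_outliers(mat, pid, target, 10)
  birth_ids <- sheet$sample_id[sheet$timepoint == "birth"]
  flagged <- mad_filter(far$values[pid, birth_ids], multiplier = 5)
  expect_true(target %in% flagged$report$excluded[[1]]$sample_id)

  near <- inject_outliers(mat, pid, target, 4)
  unflagged <- mad_filter(near$values[pid, birth_ids], multiplier = 5)
  expect_false(target %in% unflagged$report$excluded[[1]]$sample_id)

  expect_error(inject_outliers(mat, "nope", target, 1), "no such probe")
  constant <- methyl_matrix(matrix(1, 1, 4,
                                   dimnames = list("p", paste0("s", 1:4))),
                            "M")
  expect_error(inject_outliers(constant, "p", "s1", 1), "MAD")
})
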
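# Synthetic two-timepoint cohort generator. Emulates the statistical
# structure the downstream analysis assumes — two conception groups with
# realistic covariate marginals, twin pairs in the ART group, partial
# timepoint availability, 96-well plate batches and heavy-tailed M-value
# noise — so the whole pipeline is testable without access-restricted
# registry data.

#' Specify a synthetic cohort
#'
#' Defaults reproduce the marginal composition of the motivating study
#' cohort: 250 naturally conceived and 105 ART-conceived children, 14
#' in-study ART twin pairs (generated as 14 extra co-twins, i.e. 119 ART
#' children pre-deduplication), two-timepoint availability of 97.2% /
#' 76.2%, and the published smoking, BMI, parity, sex, multiple-birth and
#' maternal-age marginals per group. BMI is missing at the published NA
#' rates (5.6% natural / 2.9% ART); all other covariates are complete.
#'
#' Maternal age is drawn from a normal distribution truncated to
#' `[17, 45]` years with group means 31.3 (natural) and 33.8 (ART) and SD
#' `maternal_age_sd`. Postnatal sampling age is drawn from the study's age
#' bands (3-5, 5-10, 10-15, 15-20, 20-22 years) with the observed per-group
#' band counts as weights, uniform within a band. Children with a single
#' timepoint are split between birth-only and postnatal-only at the observed
#' per-group rates.
#'
#' @param n_natural,n_art number of children per conception group
#'   (post-deduplication for ART; co-twins are generated on top).
#' @param twin_pair_count_art number of ART twin pairs present in the sheet.
#' @param p_two_timepoints_natural,p_two_timepoints_art probability a child
#'   has samples at both timepoints.
#' @param p_birth_only_single_natural,p_birth_only_single_art probability
#'   that a single-timepoint child's sample is the birth one.
#' @param covariate_marginals named list of per-group category probabilities
#'   for `sex`, `smoking`, `bmi`, `parity` and `multiple`; see the default
#'   for the expected shape. Category probabilities must sum to 1.
#' @param maternal_age list with `mean_natural`, `mean_ART`, `sd`, `lower`,
#'   `upper` (years).
#' @param postnatal_age list with band `breaks` (years, increasing) and
#'   per-group band `weights`.
#' @param n_plates number of 96-well plates, or `NULL` to use
#'   `ceiling(n_samples / 96)`.
#' @param plate_sd SD of the per-plate random intercept in M-value units.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_natural = 250L, n_art = 105L,
                        twin_pair_count_art = 14L,
                        p_two_timepoints_natural = 243 / 250,
                        p_two_timepoints_art = 80 / 105,
                        p_birth_only_single_natural = 4 / 7,
                        p_birth_only_single_art = 1 / 25,
                        covariate_marginals = default_marginals(),
                        maternal_age = list(mean_natural = 31.3,
                                            mean_ART = 33.8, sd = 4.5,
                                            lower = 17, upper = 45),
                        postnatal_age = list(
                          breaks = c(3, 5, 10, 15, 20, 22),
                          weights = list(natural = c(53, 19, 137, 33, 4),
                                         ART = c(28, 2, 61, 10, 3))),
                        n_plates = NULL, plate_sd = 0.1, seed = 1L) {
  stopifnot(n_natural >= 0L, n_art >= 0L, twin_pair_count_art >= 0L,
            twin_pair_count_art <= n_art, plate_sd >= 0,
            maternal_age$sd > 0)
  for (p in c(p_two_timepoints_natural, p_two_timepoints_art,
              p_birth_only_single_natural, p_birth_only_single_art)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  for (cov in c("sex", "smoking", "bmi", "parity")) {
    for (grp in c("natural", "ART")) {
      pr <- covariate_marginals[[cov]][[grp]]
      if (is.null(pr)) {
        stop("covariate_marginals lacks ", cov, " probabilities for group ",
             grp)
      }
      if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9) {
        stop("category probabilities for covariate '", cov, "' (", grp,
             ") must be nonnegative and sum to 1")
      }
    }
  }
  for (grp in c("natural", "ART")) {
    pm <- covariate_marginals$multiple[[grp]]
    if (is.null(pm) || pm < 0 || pm > 1) {
      stop("covariate_marginals$multiple$", grp,
           " must be a probability in [0, 1]")
    }
    w <- postnatal_age$weights[[grp]]
    if (length(w) != length(postnatal_age$breaks) - 1L || any(w < 0)) {
      stop("postnatal_age weights for group ", grp,
           " must be nonnegative, one per band")
    }
  }
  structure(list(
    n_natural = as.integer(n_natural), n_art = as.integer(n_art),
    twin_pair_count_art = as.integer(twin_pair_count_art),
    p_two_timepoints_natural = p_two_timepoints_natural,
    p_two_timepoints_art = p_two_timepoints_art,
    p_birth_only_single_natural = p_birth_only_single_natural,
    p_birth_only_single_art = p_birth_only_single_art,
    covariate_marginals = covariate_marginals,
    maternal_age = maternal_age, postnatal_age = postnatal_age,
    n_plates = if (is.null(n_plates)) NULL else as.integer(n_plates),
    plate_sd = plate_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_marginals <- function() {
  list(
    sex = list(
      natural = c(male = 102, female = 148) / 250,
      ART = c(male = 46, female = 59) / 105
    ),
    smoking = list(
      natural = c(No = 191, Sometimes = 47, Daily = 12) / 250,
      ART = c(No = 91, Sometimes = 9, Daily = 5) / 105
    ),
    bmi = list(
      natural = c(Underweight = 7, Normal = 172, Overweight = 41,
                  Obese = 16, missing = 14) / 250,
      ART = c(Underweight = 4, Normal = 69, Overweight = 22,
              Obese = 7, missing = 3) / 105
    ),
    parity = list(
      natural = c(`0` = 125, `1` = 82, `2` = 36, `3` = 5, `4` = 2) / 250,
      ART = c(`0` = 71, `1` = 27, `2` = 7, `3` = 0, `4` = 0) / 105
    ),
    multiple = list(natural = 2 / 250, ART = 24 / 105)
  )
}

#' Per-probe ART effects and noise for the methylation simulator
#'
#' @param probe_ids character vector of unique probe IDs carrying nonzero
#'   ART effects (probes absent from the profile get effect 0).
#' @param delta_birth,delta_postnatal ART effect in M-value units per probe
#'   (recycled to `length(probe_ids)`).
#' @param noise_scale t-noise scale multiplier sigma in M-value units
#'   (default 0.49).
#' @param noise_df degrees of freedom nu of the t noise (default 10; must
#'   exceed 2 for finite variance). Total noise SD is
#'   `noise_scale * sqrt(noise_df / (noise_df - 2))`.
#' @param intercept baseline M-value (default 1.2).
#' @return list of class `effect_profile`.
#' @export
effect_profile <- function(probe_ids = character(0L), delta_birth = 0,
                           delta_postnatal = 0, noise_scale = 0.49,
                           noise_df = 10, intercept = 1.2) {
  stopifnot(noise_scale > 0, noise_df > 2)
  if (anyDuplicated(probe_ids) > 0L) stop("probe_ids must be unique")
  n <- length(probe_ids)
  structure(list(
    probe_ids = as.character(probe_ids),
    delta_birth = rep_len(delta_birth, n),
    delta_postnatal = rep_len(delta_postnatal, n),
    noise_scale = noise_scale, noise_df = noise_df, intercept = intercept
  ), class = "effect_profile")
}

# inverse-CDF truncated normal: fixed RNG draw count per call
.rtnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

.draw_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

.draw_child_covariates <- function(n, group, spec) {
  cm <- spec$covariate_marginals
  ma <- spec$maternal_age
  mean_age <- if (group == "ART") ma$mean_ART else ma$mean_natural
  bmi <- .draw_cat(n, cm$bmi[[group]])
  data.frame(
    conception = group,
    sex = .draw_cat(n, cm$sex[[group]]),
    maternal_age = round(.rtnorm(n, mean_age, ma$sd, ma$lower, ma$upper), 1L),
    smoking = .draw_cat(n, cm$smoking[[group]]),
    bmi_category = ifelse(bmi == "missing", NA_character_, bmi),
    parity = as.integer(.draw_cat(n, cm$parity[[group]])),
    stringsAsFactors = FALSE
  )
}

.draw_postnatal_age <- function(n, group, spec) {
  pa <- spec$postnatal_age
  band <- sample.int(length(pa$weights[[group]]), n, replace = TRUE,
                     prob = pa$weights[[group]])
  round(stats::runif(n, pa$breaks[band], pa$breaks[band + 1L]), 1L)
}

#' Generate a synthetic two-timepoint sample sheet
#'
#' Draws children per [cohort_spec()]: `n_natural` naturally conceived
#' children, `n_art` ART index children of which `twin_pair_count_art` get a
#' generated co-twin sharing the pair's maternal covariates and a
#' `twin_pair_id` (so the sheet holds `n_art + twin_pair_count_art` ART
#' children before [dedup_twins()]). Timepoint availability, covariates,
#' multiple-birth status and postnatal ages are drawn from the spec's
#' marginals; every sample row is assigned to a 96-well plate at random.
#' Deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return validated sample sheet data.frame, one row per blood sample.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cm <- spec$covariate_marginals

  nat <- .draw_child_covariates(spec$n_natural, "natural", spec)
  if (spec$n_natural > 0L) {
    nat$child_id <- sprintf("N%04d", seq_len(spec$n_natural))
    nat$twin_pair_id <- NA_character_
    nat$multiple_birth <- stats::runif(spec$n_natural) < cm$multiple$natural
  }

  art <- .draw_child_covariates(spec$n_art, "ART", spec)
  n_pairs <- spec$twin_pair_count_art
  if (spec$n_art > 0L) {
    art$child_id <- sprintf("A%04d", seq_len(spec$n_art))
    art$twin_pair_id <- NA_character_
    # in-study pairs are the first n_pairs index children; remaining children
    # draw the flag at the rate that restores the post-dedup marginal
    p_extra <- if (spec$n_art > n_pairs) {
      max(0, (cm$multiple$ART * spec$n_art - n_pairs) /
            (spec$n_art - n_pairs))
    } else 0
    art$multiple_birth <- stats::runif(spec$n_art) < p_extra
    if (n_pairs > 0L) {
      art$twin_pair_id[seq_len(n_pairs)] <- sprintf("TP%03d", seq_len(n_pairs))
      art$multiple_birth[seq_len(n_pairs)] <- TRUE
      cotwin <- art[seq_len(n_pairs), , drop = FALSE]  # shared maternal rows
      cotwin$child_id <- sprintf("A%04d", spec$n_art + seq_len(n_pairs))
      cotwin$sex <- .draw_cat(n_pairs, cm$sex$ART)
      art <- rbind(art, cotwin)
    }
  }

  children <- rbind(nat, art)
  if (nrow(children) == 0L) stop("empty cohort: both group sizes are zero")

  is_art <- children$conception == "ART"
  p_both <- ifelse(is_art, spec$p_two_timepoints_art,
                   spec$p_two_timepoints_natural)
  both <- stats::runif(nrow(children)) < p_both
  p_birth_only <- ifelse(is_art, spec$p_birth_only_single_art,
                         spec$p_birth_only_single_natural)
  birth_only <- !both & (stats::runif(nrow(children)) < p_birth_only)
  has_birth <- both | birth_only
  has_post <- both | (!both & !birth_only)

  birth_rows <- children[has_birth, , drop = FALSE]
  post_rows <- children[has_post, , drop = FALSE]
  post_age <- numeric(nrow(post_rows))
  for (grp in c("natural", "ART")) {
    idx <- post_rows$conception == grp
    if (any(idx)) post_age[idx] <- .draw_postnatal_age(sum(idx), grp, spec)
  }
  sample_rows <- function(ch, tp, age) {
    n <- nrow(ch)
    data.frame(
      sample_id = paste0(ch$child_id,
                         rep(if (tp == "birth") "_T0" else "_T1", n)),
      child_id = ch$child_id, timepoint = rep(tp, n),
      conception = ch$conception, sex = ch$sex,
      child_age = rep_len(age, n), multiple_birth = ch$multiple_birth,
      twin_pair_id = ch$twin_pair_id, maternal_age = ch$maternal_age,
      smoking = ch$smoking, bmi_category = ch$bmi_category,
      parity = ch$parity, plate_id = rep(NA_character_, n),
      stringsAsFactors = FALSE
    )
  }
  sheet <- rbind(sample_rows(birth_rows, "birth", NA_real_),
                 sample_rows(post_rows, "postnatal", post_age))
  if (nrow(sheet) == 0L) stop("no samples generated: availability ",
                              "probabilities exclude both timepoints")
  n_plates <- if (is.null(spec$n_plates)) {
    max(1L, ceiling(nrow(sheet) / 96))
  } else spec$n_plates
  sheet$plate_id <- sample(sprintf("P%02d", seq_len(n_plates)),
                           nrow(sheet), replace = TRUE)
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
}

#' Simulate an M-value matrix for a synthetic cohort
#'
#' Each cell follows
#' `M(probe, sample) = intercept + delta_timepoint(probe) * 1[ART]
#'  + plate_effect(plate) + sigma * T`, with `T ~ t(nu)` i.i.d. noise and
#' plate effects drawn once per plate from `Normal(0, plate_sd)` and shared
#' across probes. Deterministic under `seed`.
#'
#' @param samples validated sample sheet (every sample must carry a plate).
#' @param probes probe annotation data.frame (e.g. [default_manifest()]);
#'   rows of the matrix.
#' @param effects an [effect_profile()]; every profiled probe must be in
#'   `probes`.
#' @param spec the [cohort_spec()] (supplies `plate_sd` and the default
#'   seed).
#' @param seed RNG seed; defaults to `spec$seed + 1` so cohort and matrix
#'   draws do not share a stream.
#' @return a [methyl_matrix()] on the M scale.
#' @export
generate_methylation <- function(samples, probes, effects, spec,
                                 seed = spec$seed + 1L) {
  stopifnot(inherits(effects, "effect_profile"), inherits(spec, "cohort_spec"))
  samples <- validate_sample_sheet(samples)
  if (nrow(probes) == 0L) stop("probe set is empty")
  if (anyNA(samples$plate_id)) stop("every sample needs a plate assignment")
  missing_p <- setdiff(effects$probe_ids, probes$probe_id)
  if (length(missing_p) > 0L) {
    stop("effect profile names probe(s) absent from the manifest: ",
         paste(missing_p, collapse = ", "))
  }
  set.seed(seed)
  probe_ids <- probes$probe_id
  np <- length(probe_ids)
  ns <- nrow(samples)

  d_birth <- d_post <- setNames(rep(0, np), probe_ids)
  d_birth[effects$probe_ids] <- effects$delta_birth
  d_post[effects$probe_ids] <- effects$delta_postnatal

  plates <- unique(samples$plate_id)
  plate_eff <- setNames(stats::rnorm(length(plates), 0, spec$plate_sd),
                        plates)
  is_art <- samples$conception == "ART"
  is_birth <- samples$timepoint == "birth"
  delta_mat <- outer(d_birth, as.numeric(is_birth)) +
    outer(d_post, as.numeric(!is_birth))
  art_term <- sweep(delta_mat, 2L, as.numeric(is_art), `*`)
  noise <- matrix(effects$noise_scale * stats::rt(np * ns,
                                                  df = effects$noise_df),
                  nrow = np, ncol = ns)
  m <- effects$intercept + art_term +
    matrix(plate_eff[samples$plate_id], nrow = np, ncol = ns, byrow = TRUE) +
    noise
  dimnames(m) <- list(probe_ids, samples$sample_id)
  methyl_matrix(m, scale = "M")
}

#' Inject outliers at one probe
#'
#' Sets the listed samples' values to `median + offset_in_mads * MAD` of the
#' probe's current distribution (unscaled MAD), leaving every other cell
#' untouched. A fixture generator for exercising the median +/- k x MAD
#' filter: an offset above the filter multiplier is flagged downstream, one
#' below is not.
#'
#' @param matrix a [methyl_matrix()] on the M scale.
#' @param probe_id probe to perturb.
#' @param sample_ids samples to shift.
#' @param offset_in_mads signed offset in MAD units from the probe median.
#' @return the modified [methyl_matrix()].
#' @export
inject_outliers <- function(matrix, probe_id, sample_ids, offset_in_mads) {
  stopifnot(inherits(matrix, "methyl_matrix"))
  if (!probe_id %in% rownames(matrix$values)) {
    stop("no such probe: ", probe_id)
  }
  missing_s <- setdiff(sample_ids, colnames(matrix$values))
  if (length(missing_s) > 0L) {
    stop("no such sample(s): ", paste(missing_s, collapse = ", "))
  }
  v <- matrix$values[probe_id, ]
  med <- stats::median(v, na.rm = TRUE)
  mad_v <- stats::median(abs(v - med), na.rm = TRUE)
  if (mad_v == 0) stop("MAD of probe ", probe_id,
                       " is zero; cannot scale the offset")
  matrix$values[probe_id, sample_ids] <- med + offset_in_mads * mad_v
  matrix
}

#' Deterministic sheet with the reference study composition
#'
#' Builds, without randomness, a post-deduplication sample sheet whose
#' marginal counts equal the published cohort table: 250 naturally conceived
#' and 105 ART-conceived children; 243 / 80 with both timepoints (birth
#' totals 247 / 81, postnatal 246 / 104); sex 102 / 46 male; 2 / 24 multiple
#' births; the published smoking, BMI (incl. NA), and parity counts; group
#' maternal-age means 31.3 / 33.8 years. Covariates are assigned blockwise,
#' so joint distributions are artificial — the sheet is meant for exercising
#' [describe_cohort()] and formatting code, not for model fitting.
#'
#' @return validated sample sheet data.frame.
#' @export
study_reference_cohort <- function() {
  blocks <- function(counts) rep(names(counts), counts)
  child <- data.frame(
    child_id = c(sprintf("N%04d", 1:250), sprintf("A%04d", 1:105)),
    conception = rep(c("natural", "ART"), c(250L, 105L)),
    stringsAsFactors = FALSE
  )
  child$sex <- c(blocks(c(male = 102, female = 148)),
                 blocks(c(male = 46, female = 59)))
  child$multiple_birth <- c(rep(c(TRUE, FALSE), c(2L, 248L)),
                            rep(c(TRUE, FALSE), c(24L, 81L)))
  child$smoking <- c(blocks(c(No = 191, Sometimes = 47, Daily = 12)),
                     blocks(c(No = 91, Sometimes = 9, Daily = 5)))
  bmi_nat <- blocks(c(Underweight = 7, Normal = 172, Overweight = 41,
                      Obese = 16, missing = 14))
  bmi_art <- blocks(c(Underweight = 4, Normal = 69, Overweight = 22,
                      Obese = 7, missing = 3))
  child$bmi_category <- ifelse(c(bmi_nat, bmi_art) == "missing",
                               NA_character_, c(bmi_nat, bmi_art))
  child$parity <- as.integer(c(blocks(c(`0` = 125, `1` = 82, `2` = 36,
                                        `3` = 5, `4` = 2)),
                               blocks(c(`0` = 71, `1` = 27, `2` = 7))))
  child$maternal_age <- rep(c(31.3, 33.8), c(250L, 105L))
  # availability: natural 243 both / 4 birth-only / 3 postnatal-only;
  # ART 80 both / 1 birth-only / 24 postnatal-only
  child$avail <- c(blocks(c(both = 243, birth_only = 4, postnatal_only = 3)),
                   blocks(c(both = 80, birth_only = 1, postnatal_only = 24)))

  ages_nat <- rep(c(4, 7.5, 12.5, 17.5, 21), c(53L, 19L, 137L, 33L, 4L))
  ages_art <- rep(c(4, 7.5, 12.5, 17.5, 21), c(28L, 2L, 61L, 10L, 3L))
  has_birth <- child$avail %in% c("both", "birth_only")
  has_post <- child$avail %in% c("both", "postnatal_only")
  row_of <- function(idx, tp, ages = NULL) {
    ch <- child[idx, , drop = FALSE]
    data.frame(
      sample_id = paste0(ch$child_id, if (tp == "birth") "_T0" else "_T1"),
      child_id = ch$child_id, timepoint = tp, conception = ch$conception,
      sex = ch$sex,
      child_age = if (tp == "birth") NA_real_ else ages,
      multiple_birth = ch$multiple_birth, twin_pair_id = NA_character_,
      maternal_age = ch$maternal_age, smoking = ch$smoking,
      bmi_category = ch$bmi_category, parity = ch$parity,
      plate_id = NA_character_, stringsAsFactors = FALSE
    )
  }
  post_idx <- which(has_post)
  ages <- c(ages_nat, ages_art)  # one age per postnatal child, in group order
  sheet <- rbind(row_of(which(has_birth), "birth"),
                 row_of(post_idx, "postnatal", ages))
  sheet$plate_id <- sprintf("P%02d", ((seq_len(nrow(sheet)) - 1L) %/% 96L) + 1L)
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
}
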
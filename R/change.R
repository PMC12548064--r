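# Within-child change analysis: residualize each timepoint on technical and
# child covariates (sex, postnatal age, plate), standardize the residuals
# within each timepoint dataset, difference them per child, and regress the
# difference on ART with maternal covariates by ordinary least squares.

#' Standardized residuals from the timepoint technical model
#'
#' Fits a plate random-intercept model of one probe's M-values on child sex
#' (plus child age for postnatal data) and returns the residuals centred and
#' scaled within the dataset (mean 0, SD 1 with the n-1 denominator). The
#' standardization makes residuals comparable between the birth and
#' postnatal datasets, which are measured in different tissues; it also makes
#' the downstream change statistic invariant to any positive affine
#' rescaling of the M-values within a timepoint.
#'
#' @param y named numeric M-values (names are sample IDs).
#' @param samples sample sheet rows matching `y` (same order).
#' @param timepoint `"birth"` or `"postnatal"`.
#' @param reml passed to the mixed fit.
#' @return named numeric vector of standardized residuals.
#' @export
residualize_standardize <- function(y, samples,
                                    timepoint = c("birth", "postnatal"),
                                    reml = TRUE) {
  timepoint <- match.arg(timepoint)
  stopifnot(length(y) == nrow(samples))
  dat <- data.frame(
    y = as.numeric(y),
    sex_male = as.numeric(samples$sex == "male"),
    plate = factor(samples$plate_id)
  )
  form <- y ~ sex_male + (1 | plate)
  if (timepoint == "postnatal") {
    dat$child_age <- samples$child_age
    form <- y ~ sex_male + child_age + (1 | plate)
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      form, data = dat, REML = reml,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) NULL
  )
  r <- if (is.null(fit)) {
    stats::residuals(stats::lm(stats::as.formula(lme4::nobars(form)),
                               data = dat))
  } else {
    stats::residuals(fit)
  }
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) {
    stop("degenerate probe: residual SD is zero after residualization")
  }
  z <- (r - mean(r)) / s
  names(z) <- samples$sample_id
  z
}

#' Within-child change regression for one probe
#'
#' For every child with standardized residuals at both timepoints, forms the
#' change statistic `d = z_postnatal - z_birth` (sign configurable via
#' `direction`) and fits an ordinary linear model of `d` on ART, maternal
#' age, smoking, BMI and parity, with a two-sided Wald test on the ART
#' coefficient. Maternal covariates are taken from the child's birth row
#' (they are identical across a child's rows by construction).
#'
#' @param z_birth,z_postnatal named standardized residual vectors from
#'   [residualize_standardize()] (names are sample IDs).
#' @param samples validated sample sheet covering both timepoints.
#' @param direction `"postnatal_minus_birth"` (default) or
#'   `"birth_minus_postnatal"`; flips the sign of the outcome and hence of
#'   the reported coefficient.
#' @param min_children minimum number of complete pairs (default 10).
#' @return one-row data.frame: `beta_hat`, `se`, `ci_low`, `ci_high`,
#'   `p_raw`, `n_children`.
#' @export
within_child_change <- function(z_birth, z_postnatal, samples,
                                direction = c("postnatal_minus_birth",
                                              "birth_minus_postnatal"),
                                min_children = 10L) {
  direction <- match.arg(direction)
  samples <- validate_sample_sheet(samples)
  birth_rows <- samples[samples$timepoint == "birth", , drop = FALSE]
  post_rows <- samples[samples$timepoint == "postnatal", , drop = FALSE]
  birth_child <- birth_rows$child_id[match(names(z_birth),
                                           birth_rows$sample_id)]
  post_child <- post_rows$child_id[match(names(z_postnatal),
                                         post_rows$sample_id)]
  if (anyNA(birth_child) || anyNA(post_child)) {
    stop("residual vectors contain sample IDs absent from the sheet")
  }
  both <- intersect(birth_child, post_child)
  if (length(both) < min_children) {
    stop("only ", length(both), " children have both timepoints; need >= ",
         min_children)
  }
  d <- z_postnatal[match(both, post_child)] - z_birth[match(both, birth_child)]
  if (direction == "birth_minus_postnatal") d <- -d

  info <- birth_rows[match(both, birth_rows$child_id), , drop = FALSE]
  # children lacking a birth row cannot occur here (both timepoints required)
  dat <- data.frame(
    d = as.numeric(d),
    art = as.numeric(info$conception == "ART"),
    maternal_age = info$maternal_age,
    smoking_sometimes = as.numeric(info$smoking == "Sometimes"),
    smoking_daily = as.numeric(info$smoking == "Daily"),
    bmi_underweight = as.numeric(info$bmi_category == "Underweight"),
    bmi_overweight = as.numeric(info$bmi_category == "Overweight"),
    bmi_obese = as.numeric(info$bmi_category == "Obese"),
    parity = as.numeric(info$parity)
  )
  complete <- stats::complete.cases(dat)
  dat <- dat[complete, , drop = FALSE]
  if (nrow(dat) < min_children) {
    stop("fewer than ", min_children,
         " covariate-complete children with both timepoints")
  }
  if (stats::sd(dat$d) == 0) {
    warning("within-child differences are constant; reporting p = 1")
    return(data.frame(beta_hat = 0, se = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_raw = 1,
                      n_children = nrow(dat)))
  }
  fit <- stats::lm(d ~ ., data = dat)
  sm <- summary(fit)$coefficients
  est <- sm["art", "Estimate"]
  se <- sm["art", "Std. Error"]
  z <- est / se
  data.frame(
    beta_hat = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    p_raw = 2 * stats::pnorm(-abs(z)),
    n_children = nrow(dat)
  )
}

#' Run the within-child change analysis across the candidate probes
#'
#' Full per-probe pipeline: median +/- k x MAD outlier filtering within each
#' timepoint dataset, residualization and standardization per timepoint
#' ([residualize_standardize()]), the within-child change regression
#' ([within_child_change()]), and BH adjustment across the probe family.
#' Children with an outlying or missing value at either timepoint are
#' excluded from that probe's change model (complete-pair analysis).
#'
#' @param matrix_birth,matrix_postnatal [methyl_matrix()] objects sharing
#'   the probe set (duplicated probes are an error).
#' @param samples validated sample sheet (post twin-dedup).
#' @param manifest probe annotations; analysis restricted to shared probes.
#' @param mad_multiplier outlier-filter multiplier (default 5).
#' @param direction change sign convention, see [within_child_change()].
#' @param reml passed to the residualization fits.
#' @return data.frame, one row per probe sorted by position: annotation
#'   columns plus `beta_hat`, `se`, `ci_low`, `ci_high`, `p_raw`, `p_fdr`,
#'   `n_children`.
#' @export
run_change <- function(matrix_birth, matrix_postnatal, samples, manifest,
                       mad_multiplier = 5,
                       direction = "postnatal_minus_birth", reml = TRUE) {
  samples <- validate_sample_sheet(samples)
  matrix_birth <- as_m_scale(matrix_birth)
  matrix_postnatal <- as_m_scale(matrix_postnatal)
  probes <- intersect(manifest$probe_id,
                      intersect(rownames(matrix_birth$values),
                                rownames(matrix_postnatal$values)))
  if (length(probes) == 0L) {
    stop("no probes shared between the two matrices and the manifest")
  }
  tp_data <- lapply(
    c(birth = "birth", postnatal = "postnatal"),
    function(tp) {
      m <- if (tp == "birth") matrix_birth else matrix_postnatal
      rows <- samples[samples$timepoint == tp &
                        samples$sample_id %in% colnames(m$values), ,
                      drop = FALSE]
      if (nrow(rows) == 0L) stop("no ", tp, " samples found in its matrix")
      list(rows = rows, values = m$values[, rows$sample_id, drop = FALSE])
    }
  )
  if (length(intersect(tp_data$birth$rows$child_id,
                       tp_data$postnatal$rows$child_id)) == 0L) {
    stop("no children overlap between the birth and postnatal datasets")
  }

  rows <- lapply(probes, function(pid) {
    z <- lapply(c(birth = "birth", postnatal = "postnatal"), function(tp) {
      td <- tp_data[[tp]]
      vals <- td$values[pid, ]
      flt <- suppressWarnings(
        mad_filter(vals, multiplier = mad_multiplier, probe_id = pid))
      use <- flt$keep & is.finite(vals)
      residualize_standardize(vals[use], td$rows[use, , drop = FALSE],
                              timepoint = tp, reml = reml)
    })
    res <- within_child_change(z$birth, z$postnatal, samples,
                               direction = direction)
    res$probe_id <- pid
    res
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p_raw)
  out <- merge(manifest, out, by = "probe_id", sort = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
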
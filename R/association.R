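# Per-CpG cross-sectional association between ART and M-values at one
# timepoint: random-intercept model for the 96-well plate, two-sided Wald
# test on the ART coefficient, BH correction within the candidate family.

#' Fit the per-CpG plate random-intercept model
#'
#' Regresses one probe's M-values on the fixed-effect design with a random
#' intercept for the 96-well plate, fit by REML (set `reml = FALSE` for ML).
#' Inference on the ART coefficient is a two-sided Wald test against the
#' normal reference; the 95% CI is `beta_hat +/- 1.96 * se`. When the plate
#' variance is estimated at the boundary (zero) or the mixed fit fails, the
#' model falls back to ordinary least squares — the generalized-least-squares
#' solution at zero plate variance — with `plate_variance = 0` and
#' `converged = TRUE`.
#'
#' @param y numeric M-values, one per sample.
#' @param design numeric fixed-effect matrix from [encode_covariates()]
#'   (same row order as `y`); must contain an `art` column.
#' @param plate plate identifier per sample; at least 2 distinct plates.
#' @param reml logical; REML (default) or ML variance components.
#' @return one-row data.frame: `beta_hat`, `se`, `ci_low`, `ci_high`,
#'   `p_raw`, `n_used`, `plate_variance`, `converged`.
#' @export
fit_cpg_lmm <- function(y, design, plate, reml = TRUE) {
  stopifnot(length(y) == nrow(design), length(plate) == length(y))
  if (length(unique(plate)) < 2L) {
    stop("need at least 2 plates for the plate random effect")
  }
  if (!"art" %in% colnames(design)) stop("design must contain an 'art' column")
  dat <- data.frame(y = y, design, plate = factor(plate),
                    check.names = FALSE)
  fixed <- paste0("`", colnames(design), "`", collapse = " + ")
  n_used <- nrow(dat)

  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      stats::as.formula(paste("y ~", fixed, "+ (1 | plate)")),
      data = dat, REML = reml,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)
    )),
    error = function(e) NULL
  )
  plate_var <- if (is.null(fit)) NA_real_ else
    as.numeric(lme4::VarCorr(fit)$plate[1L])

  if (is.null(fit) || !is.finite(plate_var) || plate_var <= 0) {
    # boundary / failed mixed fit: OLS is the GLS solution at zero plate var
    ols <- tryCatch(
      stats::lm(stats::as.formula(paste("y ~", fixed)), data = dat),
      error = function(e) NULL
    )
    if (is.null(ols) || anyNA(stats::coef(ols)["art"])) {
      return(data.frame(beta_hat = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_raw = NA_real_, n_used = n_used,
                        plate_variance = NA_real_, converged = FALSE))
    }
    sm <- summary(ols)$coefficients
    est <- sm["art", "Estimate"]
    se <- sm["art", "Std. Error"]
    plate_var <- 0
  } else {
    cf <- summary(fit)$coefficients
    est <- cf["art", "Estimate"]
    se <- cf["art", "Std. Error"]
  }
  z <- est / se
  data.frame(
    beta_hat = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    p_raw = 2 * stats::pnorm(-abs(z)),
    n_used = n_used, plate_variance = plate_var, converged = TRUE
  )
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted p-value for the i-th test is
#' `min over j with rank(j) >= rank(i) of p_(j) * m / rank(j)`, capped at 1,
#' returned in the input order. Thin validation wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests in the family (default 25, the candidate
#'   promoter probe set).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 25L) {
  stopifnot(alpha > 0, alpha < 1, m >= 1L)
  alpha / m
}

#' Run the cross-sectional ART association at one timepoint
#'
#' Per candidate probe: restrict to the requested timepoint, apply the
#' median +/- k x MAD outlier filter within that timepoint dataset, drop
#' covariate-incomplete rows, fit the plate random-intercept model
#' ([fit_cpg_lmm()]) and Wald-test the ART coefficient; then BH-adjust the
#' raw p-values across the probe family. Beta-scale input is transformed to
#' M-values first. Results are sorted by genomic position.
#'
#' @param matrix a [methyl_matrix()] covering the timepoint's samples (extra
#'   samples are ignored).
#' @param samples validated sample sheet (post twin-dedup).
#' @param manifest probe annotation data.frame ([read_manifest()]); the
#'   analysis is restricted to probes present in both matrix and manifest.
#' @param timepoint `"birth"` or `"postnatal"`.
#' @param include_cell_fractions adjust for `cellfrac_*` covariates.
#' @param mad_multiplier outlier-filter multiplier (default 5).
#' @param reml passed to [fit_cpg_lmm()].
#' @return data.frame, one row per probe, sorted by position: annotation
#'   columns plus `timepoint`, `beta_hat`, `se`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_fdr`, `n_used`, `n_outliers`, `plate_variance`,
#'   `converged`.
#' @export
run_association <- function(matrix, samples, manifest,
                            timepoint = c("birth", "postnatal"),
                            include_cell_fractions = FALSE,
                            mad_multiplier = 5, reml = TRUE) {
  timepoint <- match.arg(timepoint)
  samples <- validate_sample_sheet(samples)
  matrix <- as_m_scale(matrix)
  probes <- intersect(manifest$probe_id, rownames(matrix$values))
  if (length(probes) == 0L) {
    stop("no probes shared between matrix and manifest")
  }
  tp <- samples[samples$timepoint == timepoint, , drop = FALSE]
  tp <- tp[tp$sample_id %in% colnames(matrix$values), , drop = FALSE]
  if (nrow(tp) == 0L) stop("no ", timepoint, " samples found in the matrix")
  enc <- encode_covariates(tp, timepoint = timepoint,
                           include_cell_fractions = include_cell_fractions)

  rows <- lapply(probes, function(pid) {
    vals <- matrix$values[pid, tp$sample_id]
    flt <- suppressWarnings(
      mad_filter(vals, multiplier = mad_multiplier, probe_id = pid))
    use <- flt$keep & enc$complete & is.finite(vals)
    res <- fit_cpg_lmm(vals[use], enc$design[use, , drop = FALSE],
                       tp$plate_id[use], reml = reml)
    res$probe_id <- pid
    res$n_outliers <- sum(!flt$keep)
    res
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p_raw)
  out$timepoint <- timepoint
  out <- merge(manifest, out, by = "probe_id", sort = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
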
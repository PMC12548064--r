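# Scale transforms, twin deduplication, MAD outlier filtering and covariate
# encoding ahead of the per-CpG models.

#' Beta-value / M-value transforms
#'
#' The M-value is the logit2 of the beta value, `M = log2(beta / (1 - beta))`.
#' All modelling in this package is done on the M scale, where methylation
#' differences are closer to homoscedastic; beta values are the reporting
#' scale. `beta_to_m` requires beta strictly inside (0, 1).
#'
#' @param beta numeric vector of beta values in (0, 1).
#' @param m numeric vector of M-values.
#' @return numeric vector on the other scale.
#' @examples
#' beta_to_m(0.5)   # 0
#' beta_to_m(0.8)   # 2
#' m_to_beta(2)     # 0.8
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop("beta values must lie strictly in (0, 1)")
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Convert a methylation matrix to the M scale
#'
#' @param x a [methyl_matrix()].
#' @return the matrix on the M scale (identity if already M).
#' @export
as_m_scale <- function(x) {
  stopifnot(inherits(x, "methyl_matrix"))
  if (x$scale == "M") return(x)
  methyl_matrix(beta_to_m(x$values), scale = "M")
}

#' Randomly keep one child per twin pair
#'
#' Children sharing a `twin_pair_id` are not statistically independent, so
#' one child per pair is retained at random (both of that child's timepoint
#' rows); children without a `twin_pair_id` pass through untouched. Each
#' pair must link exactly two children.
#'
#' @param samples validated sample sheet.
#' @param seed integer seed making the per-pair choice reproducible.
#' @return the sample sheet restricted to retained children.
#' @export
dedup_twins <- function(samples, seed = 1L) {
  samples <- validate_sample_sheet(samples)
  paired <- !is.na(samples$twin_pair_id)
  if (!any(paired)) return(samples)
  pair_children <- lapply(
    split(samples$child_id[paired], samples$twin_pair_id[paired]), unique)
  bad <- names(pair_children)[lengths(pair_children) != 2L]
  if (length(bad) > 0L) {
    stop("twin pair(s) not linking exactly 2 children: ",
         paste(bad, collapse = ", "))
  }
  set.seed(seed)
  keep_child <- vapply(pair_children, function(ch) sample(ch, 1L),
                       character(1L))
  drop <- paired & !(samples$child_id %in% keep_child)
  out <- samples[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median +/- k x MAD outlier filter
#'
#' Flags, within one probe and one timepoint dataset, samples whose M-value
#' falls outside `median +/- multiplier * MAD`. The MAD is the median of
#' absolute deviations from the median and is unscaled by default (no
#' 1.4826 normal-consistency constant); pass `constant = 1.4826` for the
#' scaled variant. A zero MAD (degenerate spread) excludes nothing and warns.
#' The filter is a single pass: the median and MAD are computed once on the
#' input values.
#'
#' @param values named numeric vector of M-values for one probe (names are
#'   sample IDs); at least 3 finite values required.
#' @param multiplier positive multiplier k (default 5).
#' @param constant MAD scale constant (default 1, the literal median of
#'   absolute deviations).
#' @param probe_id optional probe label carried into the report.
#' @return list with `keep` (logical mask aligned with `values`) and
#'   `report` (a one-row data.frame: `probe_id`, `n_excluded`, `median`,
#'   `mad`, `multiplier`, plus `excluded` — a data.frame of excluded
#'   sample IDs, values and direction `above`/`below`).
#' @export
mad_filter <- function(values, multiplier = 5, constant = 1,
                       probe_id = NA_character_) {
  stopifnot(is.numeric(values), multiplier > 0, constant > 0)
  finite <- is.finite(values)
  if (sum(finite) < 3L) stop("mad_filter needs at least 3 finite values")
  med <- stats::median(values[finite])
  mad_v <- constant * stats::median(abs(values[finite] - med))
  if (mad_v == 0) {
    warning("MAD is zero (degenerate spread); no samples excluded",
            if (!is.na(probe_id)) paste0(" at probe ", probe_id))
    keep <- rep(TRUE, length(values))
  } else {
    keep <- !finite | (values >= med - multiplier * mad_v &
                       values <= med + multiplier * mad_v)
  }
  keep[!finite] <- TRUE  # missing values are handled by complete-case logic
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  excluded <- data.frame(
    sample_id = ids[!keep],
    value = unname(values[!keep]),
    direction = ifelse(values[!keep] > med, "above", "below"),
    stringsAsFactors = FALSE
  )
  report <- data.frame(
    probe_id = probe_id, n_excluded = nrow(excluded), median = med,
    mad = mad_v, multiplier = multiplier, stringsAsFactors = FALSE
  )
  report$excluded <- list(excluded)
  list(keep = keep, report = report)
}

# Fixed-effect design shared by the association model. Reference levels:
# conception natural, smoking No, BMI Normal, sex female.
#' Encode model covariates
#'
#' Builds the fixed-effect design columns for the per-CpG models: ART
#' indicator (natural = 0), maternal age (years), smoking indicators
#' (reference `No`), BMI indicators (reference `Normal`), parity (integer),
#' sex indicator (reference `female`), multiple-birth indicator, child age
#' (postnatal rows only), and, optionally, estimated cell fractions with the
#' first fraction dropped as reference. Rows with any required covariate
#' missing are flagged for complete-case exclusion, never silently dropped.
#'
#' @param samples validated sample sheet rows (typically one timepoint).
#' @param timepoint `"birth"` or `"postnatal"`; child age enters the design
#'   only for postnatal data.
#' @param include_cell_fractions append `cellfrac_*` covariates (sensitivity
#'   analysis); requires those columns in the sheet.
#' @return list with `design` (numeric matrix, one row per sample, rownames
#'   sample IDs) and `complete` (logical; FALSE where a required covariate is
#'   missing).
#' @export
encode_covariates <- function(samples, timepoint = c("birth", "postnatal"),
                              include_cell_fractions = FALSE) {
  timepoint <- match.arg(timepoint)
  n <- nrow(samples)
  if (n == 0L) stop("no samples to encode")
  design <- cbind(
    art = as.numeric(samples$conception == "ART"),
    maternal_age = samples$maternal_age,
    smoking_sometimes = as.numeric(samples$smoking == "Sometimes"),
    smoking_daily = as.numeric(samples$smoking == "Daily"),
    bmi_underweight = as.numeric(samples$bmi_category == "Underweight"),
    bmi_overweight = as.numeric(samples$bmi_category == "Overweight"),
    bmi_obese = as.numeric(samples$bmi_category == "Obese"),
    parity = as.numeric(samples$parity),
    sex_male = as.numeric(samples$sex == "male"),
    multiple_birth = as.numeric(samples$multiple_birth)
  )
  if (timepoint == "postnatal") {
    design <- cbind(design, child_age = samples$child_age)
  }
  if (include_cell_fractions) {
    cf <- grep("^cellfrac_", names(samples), value = TRUE)
    if (length(cf) < 2L) {
      stop("include_cell_fractions = TRUE but the sheet has fewer than two ",
           "cellfrac_* columns")
    }
    design <- cbind(design,
                    as.matrix(samples[, cf[-1L], drop = FALSE]))
  }
  rownames(design) <- samples$sample_id
  complete <- stats::complete.cases(design)
  if (!any(complete)) stop("all samples have a missing required covariate")
  list(design = design, complete = complete)
}
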
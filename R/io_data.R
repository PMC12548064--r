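# Tabular IO: sample sheets, methylation matrices, probe manifests.
# All files are tab-separated UTF-8 text, decimal point ".", missing
# values encoded "NA", lines starting with "#" treated as comments.

SMOKING_LEVELS <- c("No", "Sometimes", "Daily")
BMI_LEVELS <- c("Underweight", "Normal", "Overweight", "Obese")
TIMEPOINTS <- c("birth", "postnatal")
CONCEPTION <- c("natural", "ART")
SEXES <- c("female", "male")

SHEET_COLUMNS <- c(
  "sample_id", "child_id", "timepoint", "conception", "sex", "child_age",
  "multiple_birth", "twin_pair_id", "maternal_age", "smoking",
  "bmi_category", "parity", "plate_id"
)

#' Validate a sample sheet
#'
#' Checks the column schema, category labels and structural invariants of a
#' sample sheet: one row per blood sample (child x timepoint), with the
#' covariates used by the association and change models. Invalid category
#' labels and broken invariants raise errors naming the offending rows, so a
#' malformed sheet is never silently truncated.
#'
#' @param samples data.frame with the columns listed in the package sample
#'   sheet schema (see [read_sample_sheet()]); optional cell-fraction columns
#'   are prefixed `cellfrac_`.
#' @return The sheet, with enumerated columns coerced to character and
#'   `multiple_birth` to logical, invisibly usable downstream.
#' @export
validate_sample_sheet <- function(samples) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(SHEET_COLUMNS, names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$child_id <- as.character(samples$child_id)
  samples$twin_pair_id <- as.character(samples$twin_pair_id)
  samples$plate_id <- as.character(samples$plate_id)
  samples$multiple_birth <- as.logical(samples$multiple_birth)

  .check_labels(samples$timepoint, TIMEPOINTS, "timepoint")
  .check_labels(samples$conception, CONCEPTION, "conception")
  .check_labels(samples$sex, SEXES, "sex")
  .check_labels(samples$smoking, SMOKING_LEVELS, "smoking")
  .check_labels(samples$bmi_category[!is.na(samples$bmi_category)],
                BMI_LEVELS, "bmi_category")

  if (anyDuplicated(samples$sample_id) > 0L) {
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  key <- paste(samples$child_id, samples$timepoint)
  if (anyDuplicated(key) > 0L) {
    stop("duplicated (child_id, timepoint): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  birth <- samples$timepoint == "birth"
  if (any(!is.na(samples$child_age[birth]))) {
    stop("child_age must be absent (NA) for birth samples; offending rows: ",
         paste(which(birth & !is.na(samples$child_age)), collapse = ", "))
  }
  if (any(is.na(samples$child_age[!birth]))) {
    stop("child_age missing for postnatal sample rows: ",
         paste(which(!birth & is.na(samples$child_age)), collapse = ", "))
  }
  if (any(!is.na(samples$parity) & samples$parity < 0)) {
    stop("parity must be a nonnegative integer")
  }
  cf <- grep("^cellfrac_", names(samples), value = TRUE)
  if (length(cf) > 0L) {
    sums <- rowSums(samples[, cf, drop = FALSE])
    bad <- which(!is.na(sums) & (sums < 0.95 | sums > 1.05))
    if (length(bad) > 0L) {
      stop("cell fractions must sum to ~1 (0.95-1.05); offending rows: ",
           paste(bad, collapse = ", "))
    }
    if (any(as.matrix(samples[, cf, drop = FALSE]) < 0, na.rm = TRUE)) {
      stop("cell fractions must be nonnegative")
    }
  }
  samples
}

.check_labels <- function(x, allowed, column) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), allowed)
  if (length(bad) > 0L) {
    rows <- which(as.character(x) %in% bad)
    stop("unknown ", column, " label(s) ",
         paste(sQuote(bad), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")",
         "; row(s): ", paste(utils::head(rows, 10L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read or write a sample sheet
#'
#' Sample sheets are tab-separated text with one row per blood sample and a
#' header row. Mandatory columns: `sample_id`, `child_id`, `timepoint`
#' (`birth`/`postnatal`), `conception` (`natural`/`ART`), `sex`, `child_age`
#' (years; postnatal rows only), `multiple_birth`, `twin_pair_id`,
#' `maternal_age` (years), `smoking` (`No`/`Sometimes`/`Daily`),
#' `bmi_category` (`Underweight`/`Normal`/`Overweight`/`Obese` or `NA`),
#' `parity`, `plate_id`. Optional estimated cell-type fractions travel in
#' `cellfrac_*` columns and must sum to approximately 1 per row.
#'
#' @param path file path.
#' @return `read_sample_sheet` returns the validated data.frame;
#'   `write_sample_sheet` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = "NA", check.names = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples a validated sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  samples <- validate_sample_sheet(samples)
  out <- samples
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE,
                                scientific = FALSE))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Construct a methylation matrix
#'
#' A light container for probes x samples methylation values with an explicit
#' scale flag. Beta values are methylated-signal fractions and must lie
#' strictly inside (0, 1) so the logit2 transform to M-values is defined;
#' M-values are unconstrained reals.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   rownames (probe IDs) and colnames (sample IDs).
#' @param scale `"beta"` or `"M"`.
#' @return An object of class `methyl_matrix` (a named list with `values`
#'   and `scale`).
#' @export
methyl_matrix <- function(values, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values)) > 0L) {
    stop("duplicated probe IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values)) > 0L) {
    stop("duplicated sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  storage.mode(values) <- "double"
  if (scale == "beta" && any(values <= 0 | values >= 1, na.rm = TRUE)) {
    stop("beta values must lie strictly in (0, 1); ",
         "0 and 1 have no M-value (log2 of 0 or Inf)")
  }
  structure(list(values = values, scale = scale), class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d probes x %d samples, %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.methyl_matrix <- function(x) dim(x$values)

#' Read or write a methylation matrix
#'
#' The on-disk format is tab-separated text with probe IDs in the first
#' column (header `probe_id`) and sample IDs as the remaining header fields.
#' The measurement scale is not stored in the matrix file and must be
#' declared by the caller (pipeline configs record it alongside the path).
#' Values round-trip through write/read to better than 12 significant
#' digits.
#'
#' @param path file path.
#' @param scale `"beta"` or `"M"`; scale of the stored values.
#' @return `read_matrix` returns a [methyl_matrix()]; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, scale = c("M", "beta")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(parts)
  if (any(width != width[1L])) {
    bad <- which(width != width[1L])[1L]
    stop("ragged row in ", path, " at line ", bad,
         ": expected ", width[1L], " fields, found ", width[bad])
  }
  header <- parts[[1L]]
  sample_ids <- header[-1L]
  body <- parts[-1L]
  probe_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- vapply(body, function(r) as.numeric(r[-1L]),
                 numeric(length(sample_ids)))
  m <- if (length(sample_ids) == 1L) matrix(vals, nrow = length(probe_ids))
       else t(vals)
  dimnames(m) <- list(probe_ids, sample_ids)
  methyl_matrix(m, scale = scale)
}

#' @rdname read_matrix
#' @param x a [methyl_matrix()].
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "methyl_matrix"))
  df <- data.frame(probe_id = rownames(x$values),
                   format(x$values, digits = 15, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Probe manifests are tab-separated text with columns `probe_id`,
#' `chromosome`, `position` (1-based hg19 coordinate), `regulatory_feature`,
#' `island_relation` and `gene`. Annotations are returned sorted by genomic
#' position. The package bundles a 25-probe manifest for the BRCA1/NBR2
#' bidirectional promoter (hg19 17:41,277,059-41,278,712), available via
#' [default_manifest()].
#'
#' @param path file path.
#' @return data.frame of typed annotations sorted by position; an empty file
#'   yields a zero-row data.frame with a warning.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = "NA",
                          colClasses = c(position = "character"))
  need <- c("probe_id", "chromosome", "position", "regulatory_feature",
            "island_relation", "gene")
  if (nrow(df) == 0L) {
    warning("manifest ", path, " contains no probes")
    empty <- as.data.frame(setNames(rep(list(character(0L)), length(need)),
                                    need))
    empty$position <- integer(0L)
    return(empty)
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(df$position))
  if (any(is.na(pos)) || any(pos != trunc(pos))) {
    stop("non-integer probe position(s) in manifest: ",
         paste(df$position[is.na(pos) | pos != trunc(pos)], collapse = ", "))
  }
  if (any(pos <= 0)) stop("probe positions must be positive")
  df$position <- as.integer(pos)
  df$chromosome <- as.character(df$chromosome)
  df <- df[order(df$position), need]
  rownames(df) <- NULL
  df
}

#' @rdname read_manifest
#' @export
default_manifest <- function() {
  read_manifest(system.file("extdata", "brca1_nbr2_manifest.tsv",
                            package = "methylong", mustWork = TRUE))
}

#' Published within-child change results for the candidate probes
#'
#' Reference table of the published within-child change regression for the
#' 25 BRCA1/NBR2 promoter CpGs (ART cohort): per-probe coefficient, 95% CI,
#' raw p-value and Benjamini-Hochberg adjusted p-value, all at the 3-decimal
#' precision of the publication. Useful as a worked example for
#' [bh_adjust()] and [render_table2()].
#'
#' @return data.frame with columns `probe_id`, `beta_hat`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_fdr`.
#' @export
reference_change_results <- function() {
  utils::read.delim(
    system.file("extdata", "brca1_nbr2_change_reference.tsv",
                package = "methylong", mustWork = TRUE),
    sep = "\t", comment.char = "#", stringsAsFactors = FALSE
  )
}
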
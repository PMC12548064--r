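# Shared fixture builders; everything is generated in code, no stored data.

# small but structurally complete cohort: twins, both timepoints, plates
small_spec <- function(seed = 42L, ...) {
  cohort_spec(n_natural = 60L, n_art = 30L, twin_pair_count_art = 4L,
              seed = seed, ...)
}

# handcrafted 3-sample sheet for IO/validation tests
tiny_sheet <- function() {
  data.frame(
    sample_id = c("C1_T0", "C1_T1", "C2_T0"),
    child_id = c("C1", "C1", "C2"),
    timepoint = c("birth", "postnatal", "birth"),
    conception = c("ART", "ART", "natural"),
    sex = c("male", "male", "female"),
    child_age = c(NA, 7.5, NA),
    multiple_birth = c(FALSE, FALSE, FALSE),
    twin_pair_id = NA_character_,
    maternal_age = c(33.1, 33.1, 29.4),
    smoking = c("No", "No", "Sometimes"),
    bmi_category = c("Normal", "Normal", "Overweight"),
    parity = c(0L, 0L, 2L),
    plate_id = c("P01", "P02", "P01"),
    stringsAsFactors = FALSE
  )
}

# single-probe manifest for fast model-level tests
one_probe_manifest <- function() default_manifest()[1L, , drop = FALSE]

# split one simulated matrix into per-timepoint matrices
split_by_timepoint <- function(mat, sheet) {
  list(
    birth = methyl_matrix(
      mat$values[, sheet$sample_id[sheet$timepoint == "birth"],
                 drop = FALSE], "M"),
    postnatal = methyl_matrix(
      mat$values[, sheet$sample_id[sheet$timepoint == "postnatal"],
                 drop = FALSE], "M")
  )
}
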
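# Descriptive cohort tables, publication-style result tables, and the
# end-to-end pipeline driver.

.age_band <- function(age) {
  cut(age, breaks = c(-Inf, 20, 25, 30, 35, Inf), right = FALSE,
      labels = c("<20", "[20,25)", "[25,30)", "[30,35)", ">=35"))
}

#' Descriptive statistics of a cohort
#'
#' Summarizes a (post twin-deduplication) sample sheet at the child level,
#' per conception group: timepoint availability, sex, type of birth
#' (singleton/multiple), maternal smoking, pre-pregnancy BMI category
#' (including missing), parity and maternal age bands — each as count and
#' percentage of the group (1 decimal) — plus group maternal-age means.
#'
#' @param samples validated sample sheet.
#' @return list of class `cohort_summary`: `table` (data.frame with columns
#'   `covariate`, `category`, `group`, `count`, `percent`), `n` (children
#'   per group) and `maternal_age_mean` (named numeric).
#' @export
describe_cohort <- function(samples) {
  samples <- validate_sample_sheet(samples)
  tps <- tapply(samples$timepoint, samples$child_id,
                function(x) length(unique(x)))
  child <- samples[!duplicated(samples$child_id), , drop = FALSE]
  child$n_timepoints <- as.integer(tps[child$child_id])
  groups <- c("natural", "ART")
  n_group <- vapply(groups, function(g) sum(child$conception == g),
                    integer(1L))
  if (any(n_group == 0L)) {
    stop("empty conception group(s): ",
         paste(groups[n_group == 0L], collapse = ", "))
  }

  cat_of <- function(covariate, values, levels) {
    do.call(rbind, lapply(groups, function(g) {
      v <- values[child$conception == g]
      counts <- vapply(levels, function(l) {
        if (l == "NA") sum(is.na(v)) else sum(!is.na(v) & v == l)
      }, integer(1L))
      data.frame(covariate = covariate, category = levels, group = g,
                 count = counts,
                 percent = round(100 * counts / sum(child$conception == g),
                                 1L),
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- rbind(
    cat_of("repeated_measure", as.character(child$n_timepoints),
           c("2", "1")),
    cat_of("sex", child$sex, c("male", "female")),
    cat_of("birth_type", ifelse(child$multiple_birth, "Multiple",
                                "Singleton"),
           c("Singleton", "Multiple")),
    cat_of("smoking", child$smoking, c(SMOKING_LEVELS, "NA")),
    cat_of("bmi_category", child$bmi_category, c(BMI_LEVELS, "NA")),
    cat_of("parity", as.character(child$parity), c("0", "1", "2", "3", "4")),
    cat_of("maternal_age_band", as.character(.age_band(child$maternal_age)),
           c("<20", "[20,25)", "[25,30)", "[30,35)", ">=35"))
  )
  rownames(tab) <- NULL
  means <- vapply(groups, function(g)
    mean(child$maternal_age[child$conception == g]), numeric(1L))
  structure(list(table = tab, n = n_group, maternal_age_mean = round(means, 1L)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d naturally conceived, %d ART-conceived children\n",
              x$n[["natural"]], x$n[["ART"]]))
  cat(sprintf("Maternal age means: %.1f (natural), %.1f (ART)\n",
              x$maternal_age_mean[["natural"]], x$maternal_age_mean[["ART"]]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

.fmt3 <- function(x) sprintf("%.3f", x)

#' Render association or change results as a publication-style table
#'
#' Produces the candidate-probe result table: probe, chromosome, position,
#' regulatory feature, island relation, gene, coefficient with 95% CI
#' formatted `"x.xxx (lo, hi)"` (3 decimals), raw p and BH-adjusted p (3
#' decimals), rows sorted by genomic position. Probes lacking annotation are
#' kept with blank annotation fields and a warning.
#'
#' @param results data.frame from [run_association()] or [run_change()]
#'   (requires `probe_id`, `beta_hat`, `ci_low`, `ci_high`, `p_raw`,
#'   `p_fdr`).
#' @param manifest probe annotations; defaults to [default_manifest()]. Set
#'   `NULL` to reuse annotation columns already present in `results`.
#' @param path optional file; when given the table is written as TSV.
#' @return the formatted data.frame (invisibly when `path` is given).
#' @export
render_table2 <- function(results, manifest = default_manifest(),
                          path = NULL) {
  if (nrow(results) == 0L) stop("no results to render")
  ann_cols <- c("chromosome", "position", "regulatory_feature",
                "island_relation", "gene")
  if (!is.null(manifest)) {
    results <- results[, setdiff(names(results), ann_cols), drop = FALSE]
    results <- merge(results, manifest, by = "probe_id", all.x = TRUE,
                     sort = FALSE)
  }
  for (col in ann_cols) {
    if (!col %in% names(results)) results[[col]] <- NA
  }
  orphans <- results$probe_id[is.na(results$position)]
  if (length(orphans) > 0L) {
    warning("probe(s) without annotation, fields left blank: ",
            paste(orphans, collapse = ", "))
  }
  out <- data.frame(
    probe_id = results$probe_id,
    chromosome = ifelse(is.na(results$chromosome), "",
                        as.character(results$chromosome)),
    position = ifelse(is.na(results$position), "",
                      as.character(results$position)),
    regulatory_feature = ifelse(is.na(results$regulatory_feature), "",
                                results$regulatory_feature),
    island_relation = ifelse(is.na(results$island_relation), "",
                             results$island_relation),
    gene = ifelse(is.na(results$gene), "", results$gene),
    estimate_95ci = sprintf("%s (%s, %s)", .fmt3(results$beta_hat),
                            .fmt3(results$ci_low), .fmt3(results$ci_high)),
    p_raw = .fmt3(results$p_raw),
    p_fdr = .fmt3(results$p_fdr),
    stringsAsFactors = FALSE
  )
  ord <- order(suppressWarnings(as.numeric(out$position)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Default end-to-end pipeline configuration
#'
#' Study-sized synthetic cohort, default effect profile (no true ART
#' effects), 5 x MAD filtering, and the default power simulation block.
#'
#' @param seed master seed for every pipeline stage.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(),          # overrides for cohort_spec()
    effects = list(),         # overrides for effect_profile()
    mad_multiplier = 5,
    direction = "postnatal_minus_birth",
    include_cell_fractions = FALSE,
    power = list(n_iter = 10000L, family_size = 25L, target_power = 0.80,
                 search = FALSE)
  )
}

.log_line <- function(con, level, msg) {
  line <- sprintf("%s %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  writeLines(line, con)
  message(line)
  invisible(line)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> twin-dedup -> outlier-filtered association (birth
#' and postnatal) -> within-child change -> power simulation, and writes all
#' tables plus a run manifest recording seeds and versions to `out_dir`.
#' Every random stage is seeded from `config$seed`, so two runs with the
#' same configuration are byte-identical.
#'
#' @param config configuration list (see [default_pipeline_config()]) or the
#'   path to a YAML file holding one.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly. Files written: `sample_sheet.tsv`,
#'   `methylation_M.tsv`, `cohort_summary.tsv`, `association_birth.tsv`,
#'   `association_postnatal.tsv`, `change.tsv`, `power.json`,
#'   `run_manifest.json`, `run.log`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    seed <- as.integer(config$seed)
    .log_line(con, "INFO", paste("master seed:", seed))

    spec <- do.call(cohort_spec, utils::modifyList(list(seed = seed),
                                                   config$cohort))
    manifest <- default_manifest()
    effects <- do.call(effect_profile, config$effects)
    sheet <- generate_cohort(spec)
    mat <- generate_methylation(sheet, manifest, effects, spec)
    .log_line(con, "INFO", sprintf(
      "simulate: %d samples (%d children), %d probes",
      nrow(sheet), length(unique(sheet$child_id)), nrow(mat$values)))
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_matrix(mat, file.path(out_dir, "methylation_M.tsv"))

    stage <- "preprocess"
    deduped <- dedup_twins(sheet, seed = seed + 2L)
    .log_line(con, "INFO", sprintf(
      "preprocess: twin dedup retained %d of %d children",
      length(unique(deduped$child_id)), length(unique(sheet$child_id))))
    summary_tab <- describe_cohort(deduped)
    utils::write.table(summary_tab$table,
                       file.path(out_dir, "cohort_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "associate"
    assoc <- lapply(c(birth = "birth", postnatal = "postnatal"),
                    function(tp) {
      res <- run_association(mat, deduped, manifest, timepoint = tp,
                             include_cell_fractions =
                               isTRUE(config$include_cell_fractions),
                             mad_multiplier = config$mad_multiplier)
      render_table2(res, manifest,
                    file.path(out_dir, paste0("association_", tp, ".tsv")))
      .log_line(con, "INFO", sprintf(
        "associate (%s): %d probes, min raw p = %.3g", tp, nrow(res),
        min(res$p_raw, na.rm = TRUE)))
      res
    })

    stage <- "change"
    birth_ids <- deduped$sample_id[deduped$timepoint == "birth"]
    post_ids <- deduped$sample_id[deduped$timepoint == "postnatal"]
    mat_birth <- methyl_matrix(mat$values[, birth_ids, drop = FALSE], "M")
    mat_post <- methyl_matrix(mat$values[, post_ids, drop = FALSE], "M")
    chg <- run_change(mat_birth, mat_post, deduped, manifest,
                      mad_multiplier = config$mad_multiplier,
                      direction = config$direction)
    render_table2(chg, manifest, file.path(out_dir, "change.tsv"))
    .log_line(con, "INFO", sprintf(
      "change (%s): %d probes, %d-%d children per probe", config$direction,
      nrow(chg), min(chg$n_children), max(chg$n_children)))

    stage <- "power"
    fam <- config$power$family_size
    alpha <- bonferroni_alpha(0.05, fam)
    .log_line(con, "INFO", sprintf(
      "power: Bonferroni-corrected threshold 0.05/%d = %g", fam, alpha))
    n_birth <- table(deduped$conception[deduped$timepoint == "birth"])
    pspec <- power_spec(n_natural = n_birth[["natural"]],
                        n_art = n_birth[["ART"]], alpha = alpha,
                        n_iter = config$power$n_iter, seed = seed + 3L)
    pres <- simulate_power(pspec)
    .log_line(con, "INFO", sprintf(
      "power: %.3f at base n = %d/%d", pres$power, pspec$n_natural,
      pspec$n_art))
    power_out <- list(alpha = alpha, family_size = fam,
                      base = list(n_natural = pspec$n_natural,
                                  n_art = pspec$n_art, power = pres$power,
                                  mc_se = pres$mc_se))
    if (isTRUE(config$power$search)) {
      mult <- required_multiplier(pspec$n_natural, pspec$n_art,
                                  target_power = config$power$target_power,
                                  spec = pspec)
      .log_line(con, "INFO", sprintf(
        "power: multiplier %.1f reaches %.0f%% power (n = %d/%d)",
        mult$multiplier, 100 * config$power$target_power,
        mult$n_natural, mult$n_art))
      power_out$search <- list(multiplier = mult$multiplier,
                               n_natural = mult$n_natural,
                               n_art = mult$n_art,
                               power = mult$result$power)
    }
    jsonlite::write_json(power_out, file.path(out_dir, "power.json"),
                         auto_unbox = TRUE, digits = NA)

    run_manifest <- list(
      package = "methylong",
      version = as.character(utils::packageVersion("methylong")),
      r_version = as.character(getRversion()),
      master_seed = seed,
      stage_seeds = list(cohort = seed, methylation = seed + 1L,
                         twin_dedup = seed + 2L, power = seed + 3L),
      config = config[setdiff(names(config), "seed")]
    )
    jsonlite::write_json(run_manifest,
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    .log_line(con, "INFO", paste("pipeline complete:", out_dir))
    out_dir
  }, error = function(e) {
    .log_line(con, "ERROR", sprintf("stage '%s' failed: %s", stage,
                                    conditionMessage(e)))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
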
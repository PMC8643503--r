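## Cohort-level association analysis: paired regional g-ratio comparison,
## patient-vs-control NfL, correlations, the elevated-NfL rule, lesion-load
## and g-ratio stratification with sensitivity thresholds, and stratified
## exact tests. All tests are two-sided at alpha = 0.05 with no
## multiple-testing correction (stated prominently in the report).

## Patients with complete records; incomplete ones are logged, not dropped
## silently.
split_cohort <- function(cohort) {
  patients <- cohort[cohort$group == "patient", , drop = FALSE]
  controls <- cohort[cohort$group == "control", , drop = FALSE]
  complete <- stats::complete.cases(
    patients[, c("nfl_pg_ml", "lesion_vol_pct_icv", "g_wml", "g_nawm")]
  )
  excluded <- patients$subject_id[!complete]
  if (length(excluded)) {
    message("excluding ", length(excluded),
            " patient(s) with incomplete records: ",
            paste(excluded, collapse = ", "))
  }
  list(patients = patients[complete, , drop = FALSE], controls = controls,
       excluded = excluded)
}

#' Stratify patients by lesion load and lesional g-ratio
#'
#' Patients are split into low (`<= load_threshold_pct`) versus substantial
#' (`>`) lesion load, and -- within the whole patient group, not per
#' stratum -- into normal (`<=` cut) versus abnormal (`>`) lesional
#' g-ratio, where the cut is the whole-cohort median unless an explicit
#' value is given. Each load stratum yields a 2x2 table of g-ratio stratum
#' against elevated NfL.
#'
#' @param cohort Cohort data.frame (see [read_cohort()]).
#' @param nfl_threshold Elevated-NfL cut-off in pg/ml; defaults to
#'   [elevated_nfl_threshold()] on the cohort's controls.
#' @param load_threshold_pct Lesion-load threshold, % ICV.
#' @param gratio_cut `"median"` or an explicit numeric cut.
#' @return List with `low_load` and `substantial_load` 2x2 matrices (rows:
#'   abnormal/normal g-ratio; columns: elevated / not elevated NfL), the
#'   `gratio_cut_value` and `nfl_threshold` used, stratum sizes, and the
#'   excluded patient ids.
#' @export
stratify_patients <- function(cohort, nfl_threshold = NULL,
                              load_threshold_pct = 0.5,
                              gratio_cut = "median") {
  parts <- split_cohort(cohort)
  patients <- parts$patients
  if (is.null(nfl_threshold)) {
    if (nrow(parts$controls) == 0) {
      stop("no controls to derive the elevated-NfL threshold from; ",
           "supply nfl_threshold")
    }
    nfl_threshold <- elevated_nfl_threshold(parts$controls$nfl_pg_ml)
  }
  cut_value <- if (identical(gratio_cut, "median")) {
    stats::median(patients$g_wml)
  } else {
    as.numeric(gratio_cut)
  }
  elevated <- patients$nfl_pg_ml > nfl_threshold
  abnormal_g <- patients$g_wml > cut_value   # "<= median" is the normal group
  substantial <- patients$lesion_vol_pct_icv > load_threshold_pct

  make_table <- function(sel) {
    tab <- matrix(c(sum(sel & abnormal_g & elevated),
                    sum(sel & abnormal_g & !elevated),
                    sum(sel & !abnormal_g & elevated),
                    sum(sel & !abnormal_g & !elevated)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(gratio = c("abnormal", "normal"),
                                  nfl = c("elevated", "not_elevated")))
    if (sum(sel) == 0) warning("a lesion-load stratum has zero patients")
    tab
  }
  list(
    low_load = make_table(!substantial),
    substantial_load = make_table(substantial),
    gratio_cut_value = cut_value,
    nfl_threshold = nfl_threshold,
    load_threshold_pct = load_threshold_pct,
    n_low = sum(!substantial),
    n_substantial = sum(substantial),
    excluded = parts$excluded
  )
}

#' Configuration for the full cohort analysis
#'
#' @param load_threshold_pct Primary lesion-load threshold (% ICV).
#' @param sensitivity_thresholds Additional thresholds the stratified
#'   analysis is repeated at.
#' @param alpha Two-sided significance level (reported, not corrected for
#'   multiplicity).
#' @param gratio_cut `"median"` or explicit numeric cut for the g-ratio
#'   strata.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(load_threshold_pct = 0.5,
                            sensitivity_thresholds = c(0.4, 0.6),
                            alpha = 0.05,
                            gratio_cut = "median") {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full cohort association analysis
#'
#' In order: paired WML-vs-NAWM g-ratio comparison (Wilcoxon signed-rank,
#' with a paired t-test reported alongside), patient-vs-control NfL
#' (Mann-Whitney U), Spearman correlations of NfL with lesion volume and
#' with lesional g-ratio, the elevated-NfL rule (control mean + 3 SD), and
#' the lesion-load/g-ratio stratified Fisher exact tests at the primary and
#' sensitivity load thresholds. Deterministic given cohort and config.
#'
#' @param cohort Cohort data.frame.
#' @param config An [analysis_config()].
#' @return Object of class `cohort_analysis_report`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  parts <- split_cohort(cohort)
  patients <- parts$patients
  controls <- parts$controls
  if (nrow(patients) == 0) stop("no complete patient records")

  paired_g <- wilcoxon_signed_rank(patients$g_wml, patients$g_nawm)
  paired_g_ttest <- tryCatch({
    tt <- stats::t.test(patients$g_wml, patients$g_nawm, paired = TRUE)
    new_stat_result(
      "Paired t-test", c(t = unname(tt$statistic)), tt$p.value,
      list(mean_diff = unname(tt$estimate),
           ci95 = unname(tt$conf.int)),
      nrow(patients),
      note = "reported alongside the rank test; the rank test is primary"
    )
  }, error = function(e) {
    new_stat_result("Paired t-test", c(t = NA_real_), 1,
                    list(mean_diff = mean(patients$g_wml - patients$g_nawm)),
                    nrow(patients),
                    note = paste("not computable:", conditionMessage(e)))
  })
  nfl_group <- mann_whitney_u(patients$nfl_pg_ml, controls$nfl_pg_ml)
  cor_nfl_volume <- spearman_rho(patients$lesion_vol_pct_icv,
                                 patients$nfl_pg_ml)
  cor_nfl_gwml <- spearman_rho(patients$g_wml, patients$nfl_pg_ml)

  nfl_threshold <- elevated_nfl_threshold(controls$nfl_pg_ml)
  n_elevated <- sum(patients$nfl_pg_ml > nfl_threshold)

  thresholds <- unique(c(config$load_threshold_pct,
                         config$sensitivity_thresholds))
  strata <- lapply(thresholds, function(thr) {
    s <- stratify_patients(cohort, nfl_threshold = nfl_threshold,
                           load_threshold_pct = thr,
                           gratio_cut = config$gratio_cut)
    s$fisher_low <- fisher_exact_2x2(s$low_load)
    s$fisher_substantial <- fisher_exact_2x2(s$substantial_load)
    s
  })
  names(strata) <- paste0("load_", thresholds)

  structure(list(
    summary = list(
      n_patients = nrow(patients), n_controls = nrow(controls),
      excluded_patients = parts$excluded,
      median_g_wml = stats::median(patients$g_wml),
      median_g_nawm = stats::median(patients$g_nawm),
      median_nfl_patients = stats::median(patients$nfl_pg_ml),
      median_nfl_controls = stats::median(controls$nfl_pg_ml),
      nfl_threshold = nfl_threshold,
      n_elevated = n_elevated,
      prop_elevated = n_elevated / nrow(patients)
    ),
    tests = list(
      paired_g_wilcoxon = paired_g,
      paired_g_ttest = paired_g_ttest,
      nfl_patients_vs_controls = nfl_group,
      spearman_nfl_lesion_volume = cor_nfl_volume,
      spearman_nfl_g_wml = cor_nfl_gwml
    ),
    strata = strata,
    config = config,
    provenance = list(
      package = "gratiokit",
      version = as.character(utils::packageVersion("gratiokit")),
      date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
      note = paste("all tests two-sided at alpha =", config$alpha,
                   "with no multiple-testing correction")
    )
  ), class = "cohort_analysis_report")
}

#' @export
print.cohort_analysis_report <- function(x, ...) {
  s <- x$summary
  cat("== Cohort g-ratio / neurofilament analysis ==\n")
  cat(sprintf("patients %d (excluded %d), controls %d\n", s$n_patients,
              length(s$excluded_patients), s$n_controls))
  cat(sprintf("median g: WML %.3f vs NAWM %.3f\n", s$median_g_wml,
              s$median_g_nawm))
  cat(sprintf("median NfL: patients %.2f vs controls %.2f pg/ml; ",
              s$median_nfl_patients, s$median_nfl_controls))
  cat(sprintf("elevated (> %.2f pg/ml): %d/%d (%.0f%%)\n", s$nfl_threshold,
              s$n_elevated, s$n_patients, 100 * s$prop_elevated))
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %-28s p = %.4g\n", nm, t$p_value))
  }
  for (nm in names(x$strata)) {
    st <- x$strata[[nm]]
    cat(sprintf("stratified @ %.1f%% ICV (low n=%d, substantial n=%d):\n",
                st$load_threshold_pct, st$n_low, st$n_substantial))
    cat(sprintf("  low:         %d/%d vs %d/%d, Fisher p = %.4g\n",
                st$low_load[1, 1], sum(st$low_load[1, ]),
                st$low_load[2, 1], sum(st$low_load[2, ]),
                st$fisher_low$p_value))
    cat(sprintf("  substantial: %d/%d vs %d/%d, Fisher p = %.4g\n",
                st$substantial_load[1, 1], sum(st$substantial_load[1, ]),
                st$substantial_load[2, 1], sum(st$substantial_load[2, ]),
                st$fisher_substantial$p_value))
  }
  cat(x$provenance$note, "\n")
  invisible(x)
}

## Flatten a stat_result for JSON.
stat_result_to_list <- function(x) {
  list(method = x$method, statistic = as.list(x$statistic),
       p_value = x$p_value, effect = x$effect, n = x$n, note = x$note)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (machine-readable, including every test result and
#' contingency table) and `report.md` (the printed human-readable summary)
#' into `dir`.
#'
#' @param report A `cohort_analysis_report`.
#' @param dir Output directory (created if needed).
#' @return The two paths, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    summary = report$summary,
    tests = lapply(report$tests, stat_result_to_list),
    strata = lapply(report$strata, function(st) {
      list(load_threshold_pct = st$load_threshold_pct,
           gratio_cut_value = st$gratio_cut_value,
           nfl_threshold = st$nfl_threshold,
           n_low = st$n_low, n_substantial = st$n_substantial,
           low_load = as.vector(st$low_load),
           substantial_load = as.vector(st$substantial_load),
           fisher_low_p = st$fisher_low$p_value,
           fisher_substantial_p = st$fisher_substantial$p_value)
    }),
    config = unclass(report$config),
    provenance = report$provenance
  )
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  md_path <- file.path(dir, "report.md")
  md <- utils::capture.output(print(report))
  writeLines(c("```", md, "```"), md_path)
  invisible(c(json_path, md_path))
}
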
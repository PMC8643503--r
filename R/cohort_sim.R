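## Synthetic cohort generator. Emulates the structure of a newly diagnosed
## relapsing-remitting MS cohort with matched healthy controls: lesion load
## (% of intracranial volume, log-normal), paired regional median g-ratios
## (truncated normal), and plasma neurofilament light chain (log-normal)
## whose location increases monotonically with lesion volume and, in
## proportion to lesion load, with lesional g-ratio -- so the qualitative
## volume/NfL and g-ratio/NfL associations hold by construction. Controls
## draw baseline NfL only.

#' Parameters of the synthetic cohort generator
#'
#' Defaults are anchored to the cohort the package emulates: control NfL
#' median 4.5 pg/ml, patient lesion-volume median 0.5% ICV, NAWM median
#' g-ratio 0.57, a paired WML-NAWM g-ratio shift of +0.036, and dependence
#' coefficients chosen so the patient NfL median is near 7.6 pg/ml with
#' roughly a quarter of patients above the control mean + 3 SD threshold.
#'
#' @param control_nfl_meanlog,control_nfl_sdlog Log-normal baseline NfL
#'   (pg/ml) shared by controls and, before dependence terms, patients.
#' @param patient_nfl_sdlog Residual log-scale NfL noise for patients.
#' @param lesion_vol_meanlog,lesion_vol_sdlog Log-normal lesion volume
#'   (% ICV).
#' @param g_nawm_mean,g_nawm_sd NAWM median g-ratio (truncated to (0, 1)).
#' @param g_diff_mean,g_diff_sd Paired WML minus NAWM g-ratio difference.
#' @param beta_volume Coefficient on `log1p(volume / 0.5)` in log-NfL.
#' @param beta_gratio Coefficient on the lesional g-ratio excess
#'   `(g_wml - g_ref)`, weighted by `volume / (volume + 0.5)` so the
#'   g-ratio effect is concentrated at substantial lesion load.
#' @param g_ref Reference lesional g-ratio for the excess term.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(control_nfl_meanlog = log(4.5),
                          control_nfl_sdlog = 0.35,
                          patient_nfl_sdlog = 0.45,
                          lesion_vol_meanlog = log(0.5),
                          lesion_vol_sdlog = 0.9,
                          g_nawm_mean = 0.574, g_nawm_sd = 0.012,
                          g_diff_mean = 0.036, g_diff_sd = 0.025,
                          beta_volume = 0.65,
                          beta_gratio = 13,
                          g_ref = 0.61) {
  structure(as.list(environment()), class = "cohort_params")
}

## Truncated normal by rejection; bounds are far tails here so this is cheap.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
  }
  out
}

#' Simulate a subject-level cohort table
#'
#' @param n_patients,n_controls Positive subject counts.
#' @param params A [cohort_params()].
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @return A data.frame with columns `subject_id`, `group`
#'   (`"patient"`/`"control"`), `nfl_pg_ml`, and -- patients only, `NA` for
#'   controls -- `lesion_vol_pct_icv`, `g_wml`, `g_nawm`.
#' @export
simulate_cohort <- function(n_patients = 73L, n_controls = 63L,
                            params = cohort_params(), seed = 1L) {
  if (n_patients <= 0 || n_controls <= 0) {
    stop("n_patients and n_controls must be positive")
  }
  p <- params
  with_local_seed(seed, {
    vol <- stats::rlnorm(n_patients, p$lesion_vol_meanlog, p$lesion_vol_sdlog)
    g_nawm <- rtruncnorm(n_patients, p$g_nawm_mean, p$g_nawm_sd)
    g_wml <- g_nawm + stats::rnorm(n_patients, p$g_diff_mean, p$g_diff_sd)
    g_wml <- pmin(pmax(g_wml, 1e-3), 1 - 1e-3)
    raise <- p$beta_volume * log1p(vol / 0.5) +
      p$beta_gratio * (g_wml - p$g_ref) * vol / (vol + 0.5)
    nfl_p <- stats::rlnorm(n_patients, p$control_nfl_meanlog + raise,
                           p$patient_nfl_sdlog)
    nfl_c <- stats::rlnorm(n_controls, p$control_nfl_meanlog,
                           p$control_nfl_sdlog)
    data.frame(
      subject_id = c(sprintf("P%03d", seq_len(n_patients)),
                     sprintf("C%03d", seq_len(n_controls))),
      group = c(rep("patient", n_patients), rep("control", n_controls)),
      nfl_pg_ml = c(nfl_p, nfl_c),
      lesion_vol_pct_icv = c(vol, rep(NA_real_, n_controls)),
      g_wml = c(g_wml, rep(NA_real_, n_controls)),
      g_nawm = c(g_nawm, rep(NA_real_, n_controls)),
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read a cohort table as CSV
#'
#' Schema: `subject_id,group,nfl_pg_ml,lesion_vol_pct_icv,g_wml,g_nawm`.
#'
#' @param cohort Cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   validated data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "nfl_pg_ml", "lesion_vol_pct_icv",
              "g_wml", "g_nawm")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(cohort$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'")
  }
  if (anyNA(cohort$nfl_pg_ml)) stop("missing NfL values are not allowed")
  cohort
}
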
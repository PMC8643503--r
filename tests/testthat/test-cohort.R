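test_that("null-configuration cohorts carry no association by construction", {
  p0 <- cohort_params(beta_volume = 0, beta_gratio = 0,
                      patient_nfl_sdlog = 0.35)
  co <- simulate_cohort(500, 500, p0, seed = 42)
  pa <- co[co$group == "patient", ]
  ct <- co[co$group == "control", ]
  ## patient and control NfL distributions identical in expectation
  expect_lt(abs(median(pa$nfl_pg_ml) - median(ct$nfl_pg_ml)),
            0.15 * median(ct$nfl_pg_ml))
  expect_lt(abs(cor(pa$lesion_vol_pct_icv, pa$nfl_pg_ml,
                    method = "spearman")), 0.1)
  expect_lt(abs(cor(pa$g_wml, pa$nfl_pg_ml, method = "spearman")), 0.1)
})

test_that("volume-only dependence creates association through volume alone", {
  pv <- cohort_params(beta_volume = 0.65, beta_gratio = 0)
  rhos <- sapply(1:200, function(i) {
    co <- simulate_cohort(73, 5, pv, seed = 5000 + i)
    pa <- co[co$group == "patient", ]
    c(v = cor(pa$lesion_vol_pct_icv, pa$nfl_pg_ml, method = "spearman"),
      g = cor(pa$g_wml, pa$nfl_pg_ml, method = "spearman"))
  })
  expect_gt(mean(rhos["v", ]), 0.3)
  expect_lt(abs(mean(rhos["g", ])), 0.05)
})

test_that("generator validates inputs and respects its bounds", {
  expect_error(simulate_cohort(0, 10), "positive")
  expect_error(simulate_cohort(10, -1), "positive")
  co <- simulate_cohort(300, 50, seed = 3)
  pa <- co[co$group == "patient", ]
  expect_true(all(pa$g_wml > 0 & pa$g_wml < 1))
  expect_true(all(pa$g_nawm > 0 & pa$g_nawm < 1))
  expect_true(all(pa$lesion_vol_pct_icv > 0))
  expect_true(all(co$nfl_pg_ml > 0))
  expect_true(all(is.na(co$g_wml[co$group == "control"])))
  ## reproducible under a fixed seed
  expect_identical(simulate_cohort(20, 20, seed = 9),
                   simulate_cohort(20, 20, seed = 9))
})

test_that("stratification splits at the whole-cohort median exactly as defined", {
  co <- fixture_cohort()
  s <- stratify_patients(co)
  expect_equal(s$n_low, 35)
  expect_equal(s$n_substantial, 38)
  expect_equal(as.vector(s$substantial_load), c(11, 2, 12, 13))
  expect_equal(as.vector(s$low_load), c(1, 3, 12, 19))
  ## the cut itself belongs to the normal group ("<= median")
  pa <- co[co$group == "patient", ]
  at_cut <- pa$g_wml == s$gratio_cut_value
  expect_true(any(at_cut))
  expect_equal(sum(pa$g_wml > s$gratio_cut_value), 36)
  expect_equal(sum(pa$g_wml <= s$gratio_cut_value), 37)
  ## cell totals sum to the stratum sizes
  expect_equal(sum(s$low_load), s$n_low)
  expect_equal(sum(s$substantial_load), s$n_substantial)
})

test_that("degenerate strata are emitted with zero cells and a warning", {
  co <- fixture_cohort()
  expect_warning(s <- stratify_patients(co, load_threshold_pct = 100),
                 "zero patients")
  expect_equal(sum(s$substantial_load), 0)
  expect_equal(sum(s$low_load), 73)
})

test_that("full analysis is deterministic and reports the printed structure", {
  co <- fixture_cohort()
  r1 <- run_full_analysis(co)
  r2 <- run_full_analysis(co)
  r1$provenance$date <- r2$provenance$date <- NULL
  expect_identical(r1[c("summary", "tests", "strata")],
                   r2[c("summary", "tests", "strata")])

  st <- r1$strata[["load_0.5"]]
  expect_equal(st$substantial_load[1, 1] / sum(st$substantial_load[1, ]),
               11 / 23)
  expect_equal(st$substantial_load[2, 1] / sum(st$substantial_load[2, ]),
               2 / 15)
  expect_lte(st$fisher_substantial$p_value, 0.05)
  expect_gt(st$fisher_low$p_value, 0.05)

  ## sensitivity thresholds rerun the same stratified analysis
  expect_setequal(names(r1$strata), c("load_0.5", "load_0.4", "load_0.6"))
  for (nm in c("load_0.4", "load_0.6")) {
    expect_lte(r1$strata[[nm]]$fisher_substantial$p_value, 0.05)
  }
})

test_that("incomplete patient records are excluded with a logged reason", {
  co <- fixture_cohort()
  co$g_wml[co$subject_id == "PS1"] <- NA
  expect_message(r <- run_full_analysis(co), "PS1")
  expect_equal(r$summary$n_patients, 72)
  expect_equal(r$summary$excluded_patients, "PS1")
})

test_that("the analysis report round-trips through JSON on disk", {
  co <- fixture_cohort()
  r <- run_full_analysis(co)
  dir <- tempfile("report")
  paths <- write_analysis_report(r, dir)
  expect_true(all(file.exists(file.path(dir, c("report.json", "report.md")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$summary$n_patients, 73)
  expect_equal(unlist(js$strata$load_0.5$substantial_load), c(11, 2, 12, 13))
  expect_equal(js$strata$load_0.5$fisher_substantial_p,
               r$strata$load_0.5$fisher_substantial$p_value, tolerance = 1e-12)
})

test_that("effect-configuration cohorts reproduce the qualitative pattern", {
  ## volume correlation stronger than the g-ratio correlation, and the
  ## g-ratio/NfL association concentrated in the substantial-load stratum
  res <- sapply(1:60, function(i) {
    co <- simulate_cohort(73, 63, seed = 7000 + i)
    r <- run_full_analysis(co, analysis_config(sensitivity_thresholds = numeric(0)))
    st <- r$strata[["load_0.5"]]
    dsub <- st$substantial_load[1, 1] / max(1, sum(st$substantial_load[1, ])) -
      st$substantial_load[2, 1] / max(1, sum(st$substantial_load[2, ]))
    dlow <- st$low_load[1, 1] / max(1, sum(st$low_load[1, ])) -
      st$low_load[2, 1] / max(1, sum(st$low_load[2, ]))
    c(rho_v = unname(r$tests$spearman_nfl_lesion_volume$statistic["rho"]),
      rho_g = unname(r$tests$spearman_nfl_g_wml$statistic["rho"]),
      dsub = dsub, dlow = dlow,
      mw_p = r$tests$nfl_patients_vs_controls$p_value)
  })
  expect_gt(mean(res["rho_v", ]), mean(res["rho_g", ]))
  expect_gt(mean(res["rho_g", ]), 0)
  expect_gt(mean(res["dsub", ]), mean(res["dlow", ]))
  expect_lt(median(res["mw_p", ]), 0.001)   # patients' NfL clearly elevated
})
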
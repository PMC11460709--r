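tables <- laao_cohort_tables()

test_that("bundled cohort tables have the expected shape", {
  expect_equal(nrow(tables$table1), 20L)
  expect_equal(sum(tables$table1$outcome == "DRT"), 10L)
  expect_equal(nrow(tables$table2), 20L)
  expect_equal(nrow(tables$table3), 20L)
  expect_equal(nrow(tables$table4), 20L)
  # 20 implanted + 13 ridge-covering poses = 33 configurations
  expect_equal(20L + sum(!is.na(tables$table1$size_pr_mm)), 33L)
})

test_that("risk descriptors apply the stated strict thresholds", {
  rec <- data.frame(cycle_mean = c(0.10, 0.3, 0.19),
                    max_ecap = c(1.42, 0.2, 0.5),
                    pct_attached = c(12, 2, 10),
                    recirculation = c(TRUE, FALSE, FALSE))
  risk <- build_risk_table(rec)
  expect_equal(risk$low_avg_velocity, c(TRUE, FALSE, TRUE))
  expect_equal(risk$high_ecap, c(TRUE, FALSE, FALSE))     # strict >
  expect_equal(risk$high_platelet_adhesion, c(TRUE, FALSE, FALSE))  # 10 -> no
  expect_false(any(unlist(build_risk_table(
    data.frame(cycle_mean = 0.3, max_ecap = 0.2, pct_attached = 2,
               recirculation = FALSE)))))
  expect_error(build_risk_table(rec[, -2]), "missing metric")
  rec_na <- rec; rec_na$max_ecap[2] <- NA
  expect_error(build_risk_table(rec_na), "record 2")
})

test_that("group summaries reproduce the printed cohort arithmetic", {
  t1 <- tables$table1
  la <- cohort_summary(t1, "la_vol_ml", "outcome")
  expect_equal(la$mean[la$group == "control"], 163.6)
  laa <- cohort_summary(t1, "laa_vol_ml", "outcome")
  expect_equal(laa$mean[laa$group == "control"], 12.75)
  expect_equal(round(laa$mean[laa$group == "DRT"], 2), 15.30)
  # single-record group: sd flagged NA
  one <- cohort_summary(t1[1, ], "la_vol_ml", "outcome")
  expect_true(is.na(one$sd))
  # missing entries excluded and counted
  pr <- cohort_summary(t1, "size_pr_mm", "outcome")
  expect_equal(sum(pr$n), 13L)
  expect_equal(sum(pr$n_missing), 7L)
})

test_that("threshold counts recover the printed sub-threshold tally", {
  n_slow <- threshold_counts(tables$table2,
                             function(d) d$cyc_post_mean < 0.2)
  expect_equal(n_slow, 9L)
  expect_equal(threshold_counts(tables$table2, function(d) rep(FALSE, nrow(d))),
               0L)
  high <- tables$table3$max_post[tables$table3$outcome == "control"]
  expect_equal(round(mean(high[high > 0.5]), 2), 1.25)
})

test_that("concordance scores descriptor-outcome agreement", {
  rows <- data.frame(low_avg_velocity = c(TRUE, TRUE),
                     recirculation = c(TRUE, TRUE),
                     high_ecap = c(TRUE, TRUE),
                     high_platelet_adhesion = c(TRUE, TRUE))
  cc <- concordance(rows, c("DRT", "control"))
  expect_equal(cc$agreement, c(4L, 0L))
  expect_error(concordance(rows, "DRT"), "one outcome per risk row")
  expect_error(concordance(rows, c("DRT", NA)), "missing outcome")
})

test_that("printed overview table yields the published concordance tallies", {
  risk <- risk_table_from_printed(tables$table4, "post")
  expect_equal(nrow(risk), 20L)
  cc <- concordance(risk[, 3:6], risk$outcome)
  expect_equal(cc$n_complete, 5L)
  expect_equal(cc$n_at_least_3, 9L)
  # order invariance
  perm <- sample(nrow(risk))
  cc2 <- concordance(risk[perm, 3:6], risk$outcome[perm])
  expect_equal(cc2$n_complete, cc$n_complete)
  expect_equal(cc2$n_at_least_3, cc$n_at_least_3)
})

test_that("risk-table construction is idempotent on complete records", {
  rec <- data.frame(cycle_mean = c(0.1, 0.25), max_ecap = c(0.7, 0.3),
                    pct_attached = c(15, 3), recirculation = c(TRUE, FALSE))
  r1 <- build_risk_table(rec)
  r2 <- build_risk_table(cbind(rec, r1))
  expect_identical(r1, r2)
})

test_that("pipeline driver handles empty configs and is deterministic", {
  expect_warning(rep0 <- run_pipeline(list(configurations = list())),
                 "empty configuration")
  expect_equal(nrow(rep0$records), 0L)
  cfg <- list(atrium = list(mesh_edge_length = 4),
              flow = list(grid_n = 10L),
              transport = FALSE,
              configurations = list(
                list(name = "implanted", device_type = "plug", size = 24,
                     depth = 8)),
              seed = 3L)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$records), 1L)
  expect_true(all(c("cycle_mean", "max_ecap", "pr_covered") %in%
                    names(r1$records)))
})
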
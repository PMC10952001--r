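z001_parts <- function(config = grading_config()) {
  g <- z001_group()
  ev <- compute_eigenvalues(cluster_pools(partition_group(g)), non_ntc(g))
  list(ev = ev, geo = compute_derived_geometry(ev), config = config)
}

test_that("configuration validation rejects out-of-range thresholds", {
  expect_s3_class(grading_config(), "kasp_config")
  expect_error(grading_config(ntc_alpha = 1.2))
  expect_error(grading_config(spec_bins = c(0.3, 0.2, 0.4)))
  expect_error(grading_config(het_divisor = 0))
})

test_that("configurations round-trip through JSON and YAML", {
  cfg <- grading_config(ntc_alpha = 0.35, spec_bins = c(0.1, 0.2, 0.3))
  for (ext in c(".json", ".yaml")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_grading_config(cfg, tf)
    expect_equal(read_grading_config(tf), cfg)
  }
})

test_that("the reference group has a quiet NTC and top-tier statuses", {
  p <- z001_parts()
  expect_false(ntc_significance(p$ev, p$config))
  st <- derive_primer_status(p$ev, p$geo, p$config)
  expect_equal(st$red, status("Higher", "Higher", "None"))
  expect_equal(st$blue, status("Higher", "Higher", "None"))
  res <- grade_group(p$ev, p$geo, p$config)
  expect_equal(res$grade, 0L)
  expect_equal(res$rating, "Excellent")
  expect_equal(res$matched_rule, "0a")
})

test_that("an NTC center at the signal maximum is always significant", {
  p <- z001_parts()
  ev <- p$ev
  ev[["ntcx"]] <- ev[["hex_max"]]
  ev[["ntcy"]] <- ev[["fam_max"]]
  expect_true(ntc_significance(ev, p$config))
  expect_true(ntc_significance(ev, grading_config(ntc_alpha = 0.95)))
  # without NTC wells significance is vacuously false
  ev2 <- p$ev
  attr(ev2, "sizes")[["NTC"]] <- 0L
  expect_false(ntc_significance(ev2, p$config))
})

test_that("missing clusters degrade the affected primer to Lower/Lower", {
  p <- z001_parts()
  ev <- p$ev
  attr(ev, "sizes")[["1"]] <- 0L
  st <- derive_primer_status(ev, p$geo, p$config)
  expect_equal(st$red$efficiency, "Lower")
  expect_equal(st$red$specificity, "Lower")
  expect_equal(st$red$competitiveness, "None")
  expect_equal(st$blue$efficiency, "Higher")
})

test_that("grading is invariant to rescaling the fluorescence values", {
  g <- z001_group()
  for (s in c(0.2, 5)) {
    g2 <- g; g2$x <- g$x * s; g2$y <- g$y * s
    ev <- compute_eigenvalues(cluster_pools(partition_group(g2)), non_ntc(g2))
    res <- grade_group(ev, compute_derived_geometry(ev))
    expect_equal(res$grade, 0L)
    expect_equal(res$matched_rule, "0a")
  }
})

test_that("every encoded rule row maps to its printed grade", {
  rules <- kasp_grade_rules()
  for (i in seq_len(nrow(rules))) {
    comp <- function(x) if (x == "Any") "Weaker" else x
    red <- status(rules$r_eff[i], rules$r_spec[i], comp(rules$r_comp[i]))
    blue <- status(rules$b_eff[i], rules$b_spec[i], comp(rules$b_comp[i]))
    expect_equal(grade_from_status(red, blue)$grade, rules$grade[i],
                 info = rules$rule[i])
  }
  # anchor rows of the published criteria table
  hh <- status("Higher", "Higher", "None")
  hhs <- status("Higher", "Higher", "Stronger")
  ll <- status("Lower", "Lower", "None")
  expect_equal(grade_from_status(hh, hh)$grade, 0L)
  expect_equal(grade_from_status(status("Higher", "Worse", "None"), hh)$grade, 1L)
  expect_equal(grade_from_status(hhs, hhs)$grade, 1L)
  expect_equal(grade_from_status(status("Higher", "Weaker", "None"), hh)$grade, 2L)
  expect_equal(grade_from_status(hhs, hh)$grade, 2L)
  expect_equal(grade_from_status(ll, ll)$grade, 3L)
  # all-Lower maps to Poor whatever the competitiveness
  for (c1 in c("None", "Stronger", "Weaker")) {
    expect_equal(grade_from_status(status("Lower", "Lower", c1),
                                   status("Lower", "Lower", c1))$grade, 3L)
  }
})

test_that("asymmetric orientations keep their printed grades", {
  hh <- status("Higher", "Higher", "None")
  # red Worse is Good, blue Worse is Fair, as printed
  expect_equal(grade_from_status(status("Higher", "Worse", "None"), hh)$grade, 1L)
  expect_equal(grade_from_status(hh, status("Higher", "Worse", "None"))$grade, 2L)
})

test_that("the whole status space grades into 0-3 with override to 2 or 3", {
  combos <- all_status_combinations()
  for (red in combos) {
    for (blue in combos) {
      res <- grade_from_status(red, blue)
      expect_true(res$grade %in% 0:3)
      over <- grade_from_status(red, blue, ntc_significant = TRUE)
      expect_true(over$grade %in% 2:3)
      expect_equal(over$grade == 3L, res$grade == 3L)
    }
  }
})

test_that("unlisted combinations fall back to Fair and are flagged", {
  res <- grade_from_status(status("Higher", "Lower", "None"),
                           status("Lower", "Weaker", "None"))
  expect_equal(res$grade, 2L)
  expect_equal(res$matched_rule, "fallback")
})
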
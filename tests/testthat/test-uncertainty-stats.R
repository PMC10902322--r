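test_that("chi-squared goodness of fit matches the closed form", {
  ts <- chisq_two_level(538, 473)
  expect_equal(ts$chi2, 65^2 / 1011)
  expect_equal(ts$chi2, 4.18, tolerance = 0.001)
  expect_equal(ts$sig_code, "*")

  ts <- chisq_two_level(14, 26)
  expect_equal(ts$chi2, 144 / 40)
  expect_true(ts$p_value <= 0.08 && ts$p_value > 0.05)
  expect_equal(ts$sig_code, "m.s.")

  expect_equal(chisq_two_level(321, 128)$sig_code, "****")
  expect_error(chisq_two_level(0, 0), "undefined")
})

test_that("chi-squared agrees with the stats engine oracle", {
  for (ab in list(c(538, 473), c(5, 17), c(321, 128), c(7, 0))) {
    ours <- chisq_two_level(ab[1], ab[2])
    ref <- suppressWarnings(stats::chisq.test(ab, p = c(0.5, 0.5)))
    expect_equal(ours$chi2, unname(ref$statistic))
    expect_equal(ours$p_value, unname(ref$p.value))
  }
})

test_that("chi-squared is symmetric, zero at ties, monotone in |a - b|", {
  expect_equal(chisq_two_level(19, 34)$chi2, chisq_two_level(34, 19)$chi2)
  ts <- chisq_two_level(12, 12)
  expect_equal(ts$chi2, 0)
  expect_equal(ts$sig_code, "n.s.")
  tot <- 100
  chis <- vapply(0:50, function(d) chisq_two_level(50 + d, 50 - d)$chi2,
                 numeric(1))
  expect_true(all(diff(chis) > 0))
})

test_that("significance codes honour all thresholds", {
  p <- c(5e-5, 1e-4, 5e-4, 1e-3, 0.005, 0.01, 0.03, 0.05, 0.07, 0.08, 0.2)
  expect_equal(sig_code(p),
               c("****", "****", "***", "***", "**", "**", "*", "*",
                 "m.s.", "m.s.", "n.s."))
})

test_that("percentages round half-up as printed", {
  # 121/222 = 54.50 -> 55 and 19/40 = 47.5 -> 48
  cl <- classify_records(expand_matrix(the_matrix, seed = 1), the_kb)
  sp <- rate_table(cl, "species")
  expect_equal(sp$pct_mis[sp$group == "Hedera hibernica"], 55)
  expect_equal(sp$pct_mis[sp$group == "Hedera azorica"], 48)
})

test_that("a single correct record rates 100% correct", {
  cl <- data.frame(record_id = "r1", category = "correct",
                   original_key = "Hedera helix",
                   revised_key = "Hedera helix")
  rt <- rate_table(cl, "all")
  expect_equal(rt$pct_correct, 100)
  expect_equal(rt$pct_mis + rt$pct_noiden + rt$pct_hard + rt$pct_soft, 0)
})

test_that("per-row percentages reconcile within rounding slack", {
  cl <- classify_records(expand_matrix(the_matrix, seed = 3), the_kb)
  for (grouping in c("all", "species")) {
    rt <- rate_table(cl, grouping)
    gap <- abs(rt$pct_mis + rt$pct_noiden + rt$pct_hard + rt$pct_soft -
                 rt$pct_incorrect)
    expect_true(all(gap <= 2), label = grouping)
    expect_equal(rt$n_correct + rt$n_incorrect, rt$n)
  }
})

test_that("uncertainty and country groupings use record regions", {
  g <- generate_occurrences(real_structure_config(n_per_species = 60,
                                                  seed = 21))
  cl <- classify_records(g$records, the_kb)
  unc <- suppressWarnings(rate_table(cl, "uncertainty", records = g$records,
                                     region_table = the_regions))
  expect_setequal(unc$group, c("low", "high"))
  expect_equal(sum(unc$n), nrow(g$records))
  ctry <- rate_table(cl, "country", records = g$records,
                     region_table = the_regions)
  expect_equal(sum(ctry$n), nrow(g$records))
  expect_true("Spain" %in% ctry$group)
})

test_that("GLM recovers a unit log-odds contrast on a two-level toy", {
  # species B has error odds exactly e times those of species A
  p1 <- 0.3
  p2 <- stats::plogis(stats::qlogis(p1) + 1)
  cfg <- generator_config(
    regions = list(
      list(region_key = "A-land", island_group = NA, pool = "Hedera alpha",
           bbox = c(0, 1, 0, 1), n_records = 4000),
      list(region_key = "B-land", island_group = NA, pool = "Hedera beta",
           bbox = c(0, 1, 0, 1), n_records = 4000)),
    name_model = list(
      "Hedera alpha" = plain_name_model("Hedera alpha", 1 - p1),
      "Hedera beta" = plain_name_model("Hedera beta", 1 - p2)),
    seed = 77)
  g <- generate_occurrences(cfg)
  cl <- classify_records(g$records, the_kb)
  fit <- fit_error_glm(cl, g$records,
                       toy_region_table(c("A-land", "B-land"), c(1, 1)))
  expect_equal(fit$reference_level, "Hedera alpha")
  co <- fit$coefficients
  b <- co$estimate[co$term == "speciesHedera beta"]
  se <- co$std_error[co$term == "speciesHedera beta"]
  expect_lt(abs(b - 1), 3.5 * se)
  expect_false(fit$separation)
})

test_that("GLM is calibrated under the null", {
  # identical error probability everywhere: all non-intercept p-values
  # exceed 0.05 in at least 90 of 100 seeded replicates
  nm <- list("Hedera alpha" = plain_name_model("Hedera alpha", 0.7),
             "Hedera beta" = plain_name_model("Hedera beta", 0.7))
  rtab <- toy_region_table(c("R1", "R2", "R3"), c(1, 2, 1))
  pass <- 0
  for (i in 1:100) {
    cfg <- generator_config(
      regions = list(
        list(region_key = "R1", island_group = NA, pool = "Hedera alpha",
             bbox = c(0, 1, 0, 1), n_records = 200),
        list(region_key = "R2", island_group = NA,
             pool = c("Hedera alpha", "Hedera beta"),
             bbox = c(0, 1, 0, 1), n_records = 400),
        list(region_key = "R3", island_group = NA, pool = "Hedera beta",
             bbox = c(0, 1, 0, 1), n_records = 200)),
      name_model = nm, seed = 11000 + i)
    g <- generate_occurrences(cfg)
    cl <- classify_records(g$records, the_kb)
    fit <- suppressWarnings(fit_error_glm(cl, g$records, rtab))
    pv <- fit$coefficients$p_value[fit$coefficients$term != "(Intercept)"]
    if (all(pv > 0.05)) pass <- pass + 1
  }
  expect_gte(pass, 90)
})

test_that("complete separation is flagged but estimates returned", {
  cfg <- generator_config(
    regions = list(
      list(region_key = "A-land", island_group = NA, pool = "Hedera alpha",
           bbox = c(0, 1, 0, 1), n_records = 60),
      list(region_key = "B-land", island_group = NA, pool = "Hedera beta",
           bbox = c(0, 1, 0, 1), n_records = 60)),
    name_model = list(
      "Hedera alpha" = plain_name_model("Hedera alpha", 1),
      "Hedera beta" = plain_name_model("Hedera beta", 0)),
    seed = 5)
  g <- generate_occurrences(cfg)
  cl <- classify_records(g$records, the_kb)
  expect_warning(
    fit <- fit_error_glm(cl, g$records,
                         toy_region_table(c("A-land", "B-land"), c(1, 1))),
    "separation")
  expect_true(fit$separation)
  expect_true(is.finite(sum(fit$coefficients$estimate)))
})
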
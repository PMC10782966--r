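test_that("student_t handles identical, degenerate and typical inputs", {
  id <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  expect_equal(id$df, 4)
  # zero pooled variance, equal means
  expect_equal(student_t(c(2, 2), c(2, 2))$p_value, 1)
  # zero pooled variance, unequal means: degenerate path
  expect_warning(res <- student_t(c(0, 0, 0, 0), c(1, 1, 1, 1)), "degenerate|variance")
  expect_equal(res$p_value, 0)
  expect_error(student_t(1, c(1, 2)), ">= 2")
})

test_that("student_t p matches an independent t-CDF evaluation", {
  a <- c(2.1, 2.5, 2.3)
  b <- c(3.9, 4.2, 4.0)
  res <- student_t(a, b)
  expect_equal(res$p_value, oracle_t_pvalue(res$statistic, res$df),
               tolerance = 1e-8)
  # and agrees with the standard equal-variance test
  expect_equal(res$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value)
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(4)
    y <- rnorm(5, mean = runif(1, -2, 2))
    r <- student_t(x, y)
    expect_equal(r$p_value, oracle_t_pvalue(r$statistic, r$df),
                 tolerance = 1e-8)
  }
})

test_that("log2 fold change follows the stated sign convention", {
  expect_equal(log2_fc(c(0, 2), c(2, 4)), 2)
  expect_equal(log2_fc(c(1, 1), c(1, 1)), 0)
  x <- rnorm(3)
  y <- rnorm(3)
  expect_equal(log2_fc(x, y), -log2_fc(x, y, convention = "A_over_B"))
})

test_that("differential_table recovers planted effects and controls errors", {
  sim <- make_two_group_sim(n_lipids = 194, n_signal = 20, delta = 3,
                            sigma = 0.5, seed = 21)
  n <- log2_median_normalize(sim$matrix)
  tbl <- differential_table(n, a = list(salinity = 13), b = list(salinity = 20))
  planted <- sim$truth$planted$lipid_id
  hits <- tbl$significant[match(planted, tbl$lipid_id)]
  expect_gte(sum(hits), 18)
  # planted shifts are up in B (the 20% condition) with positive log2 FC
  expect_true(all(tbl$direction[match(planted, tbl$lipid_id)][hits] == "up_in_B"))
  # null false positives consistent with alpha = 0.05 (binomial 3 SD bound)
  n_null <- nrow(tbl) - length(planted)
  fp <- sum(tbl$significant & !tbl$lipid_id %in% planted)
  expect_lte(fp, 0.05 * n_null + 3 * sqrt(n_null * 0.05 * 0.95))
  # invariant to sample and lipid order
  perm <- sample(nrow(sim$matrix$values))
  m_perm <- intensity_matrix(
    sim$matrix$values[perm, rev(colnames(sim$matrix$values))],
    sample_meta = sim$matrix$sample_meta
  )
  tbl_perm <- differential_table(log2_median_normalize(m_perm),
                                 a = list(salinity = 13),
                                 b = list(salinity = 20))
  reord <- match(tbl$lipid_id, tbl_perm$lipid_id)
  expect_equal(tbl_perm$p_value[reord], tbl$p_value)
  expect_equal(tbl_perm$log2_fc[reord], tbl$log2_fc)
  # guards
  expect_error(
    differential_table(n, a = list(salinity = 13), b = list(salinity = 13)),
    "overlap"
  )
  expect_error(differential_table(sim$matrix, a = list(salinity = 13),
                                  b = list(salinity = 20)), "log2_median")
})

test_that("stricter thresholds always select a subset", {
  sim <- make_two_group_sim(n_lipids = 100, n_signal = 15, delta = 2.2,
                            sigma = 0.8, seed = 31)
  n <- log2_median_normalize(sim$matrix)
  loose <- differential_table(n, list(salinity = 13), list(salinity = 20),
                              p_threshold = 0.05, fc_threshold = 1.5)
  strict <- differential_table(n, list(salinity = 13), list(salinity = 20),
                               p_threshold = 0.01, fc_threshold = 2.5)
  expect_true(all(strict$lipid_id[strict$significant] %in%
                    loose$lipid_id[loose$significant]))
  # doubling the fc threshold never grows the selection
  doubled <- differential_table(n, list(salinity = 13), list(salinity = 20),
                                p_threshold = 0.05, fc_threshold = 3)
  expect_lte(sum(doubled$significant), sum(loose$significant))
})

test_that("lipids with too few replicates are untestable and excluded", {
  sim <- make_two_group_sim(n_lipids = 20, seed = 5)
  vals <- sim$matrix$values
  vals[1, sim$matrix$sample_meta$salinity == 13] <- c(NA, NA, vals[1, 3])
  m <- intensity_matrix(vals, sample_meta = sim$matrix$sample_meta)
  tbl <- differential_table(log2_median_normalize(m),
                            a = list(salinity = 13), b = list(salinity = 20))
  expect_true(tbl$untestable[1])
  expect_false(tbl$significant[1])
  expect_true(is.na(tbl$p_value[1]))
})

test_that("subclass composition reproduces the charge roll-up arithmetic", {
  # 15 elevated species: 4 PE, 4 PG, 3 CL, 4 DG
  calls <- tibble::tibble(
    lipid_class = rep(c("PE", "PG", "CL", "DG"), c(4, 4, 3, 4)),
    significant = TRUE,
    direction = "up_in_B"
  )
  comp <- subclass_composition(calls, direction = "up")
  expect_equal(comp$n, 15)
  anionic <- comp$by_charge$percent[comp$by_charge$charge_class == "anionic"]
  zwit <- comp$by_charge$percent[comp$by_charge$charge_class == "zwitterionic"]
  expect_equal(round_percent(anionic), 47) # PG + CL = 7/15
  expect_equal(round_percent(zwit), 27)    # PE = 4/15
  expect_equal(sum(comp$by_class$count), 15)
  expect_equal(sum(comp$by_class$percent), 100)
  # empty significant set: no division by zero
  empty <- subclass_composition(
    tibble::tibble(lipid_class = "PG", significant = FALSE, direction = "none")
  )
  expect_equal(empty$n, 0)
  expect_equal(nrow(empty$by_class), 0)
})

test_that("summarize_counts reproduces headline percentages", {
  calls <- tibble::tibble(
    significant = rep(c(TRUE, FALSE), c(76, 118)),
    direction = c(rep("up_in_B", 74), rep("down_in_B", 2), rep("none", 118))
  )
  s <- summarize_counts(calls, detected_total = 194)
  expect_equal(s$n_significant, 76)
  expect_equal(round_percent(s$percent_of_detected), 39)
  expect_equal(round_percent(s$percent_up), 97)
  zero <- summarize_counts(
    tibble::tibble(significant = logical(194), direction = rep("none", 194)),
    194
  )
  expect_equal(zero$n_significant, 0)
  expect_equal(zero$percent_of_detected, 0)
  expect_true(is.na(zero$percent_up))
  expect_error(summarize_counts(calls, 10), "smaller")
})

test_that("anova screen reduces to the t-test for two groups and finds planted signal", {
  sim <- make_two_group_sim(n_lipids = 30, n_signal = 5, delta = 2,
                            sigma = 0.5, seed = 41)
  n <- log2_median_normalize(sim$matrix)
  screen <- anova_screen(n, "salinity", k = 30)
  tbl <- differential_table(n, list(salinity = 13), list(salinity = 20))
  reord <- match(tbl$lipid_id, screen$lipid_id)
  expect_equal(screen$p_value[reord], tbl$p_value, tolerance = 1e-12)
  expect_equal(screen$f_statistic[reord], tbl$statistic^2, tolerance = 1e-12)

  # planted 10 strongly shifted lipids among 200 all appear in the top 50
  sim2 <- make_two_group_sim(n_lipids = 200, n_signal = 10, delta = 4,
                             sigma = 0.5, seed = 42)
  top50 <- anova_screen(log2_median_normalize(sim2$matrix), "salinity", k = 50)
  expect_true(all(sim2$truth$planted$lipid_id %in% top50$lipid_id))

  expect_equal(nrow(anova_screen(n, "salinity", k = 0)), 0)
  expect_warning(anova_screen(n, "salinity", k = 1000), "returning all")
})

test_that("null p-values are uniform", {
  sim <- make_two_group_sim(n_lipids = 400, seed = 51)
  tbl <- differential_table(log2_median_normalize(sim$matrix),
                            a = list(salinity = 13), b = list(salinity = 20))
  ks <- stats::ks.test(tbl$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})
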
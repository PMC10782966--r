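test_that("total-intensity normalization gives per-mode compositions", {
  m <- make_tiny_matrix()
  tn <- total_intensity_normalize(m)
  expect_identical(tn$state, "total_normalized")
  # negative-mode block (PG, PE): sample s1 = (2, 8) -> (0.2, 0.8)
  expect_equal(unname(tn$values[1:2, "s1"]), c(0.2, 0.8))
  # both mode blocks sum to 1 in every sample
  expect_silent(validate_state(tn))
  # scale invariance: multiplying one sample's raw values by 10 changes nothing
  m2 <- m
  m2$values[, "s1"] <- m2$values[, "s1"] * 10
  expect_equal(total_intensity_normalize(m2)$values, tn$values)
  expect_error(total_intensity_normalize(tn), "raw")
})

test_that("log2-median normalization centers each sample at zero", {
  values <- matrix(c(4, 8, 16, 2, 2, 2), ncol = 2,
                   dimnames = list(c("PG(16:0/18:1)", "PG(16:0/16:0)",
                                     "PE(16:0/18:1)"), c("s1", "s2")))
  m <- intensity_matrix(values)
  n <- log2_median_normalize(m)
  expect_identical(n$state, "log2_median")
  expect_equal(unname(n$values[, "s1"]), c(-1, 0, 1))
  expect_silent(validate_state(n))
  # a constant multiplicative factor between samples is absorbed
  m2 <- intensity_matrix(cbind(s1 = values[, 1], s2 = values[, 1] * 7))
  n2 <- log2_median_normalize(m2)
  expect_equal(n2$values[, "s1"], n2$values[, "s2"])
  # nonpositive intensity is an error naming coordinates, no pseudocount
  values[2, 1] <- 0
  expect_error(log2_median_normalize(intensity_matrix(values)),
               "PG\\(16:0/16:0\\), s1")
  # ... unless the zero substitute is explicitly enabled
  expect_silent(validate_state(
    log2_median_normalize(intensity_matrix(values), zero_substitute = TRUE)
  ))
})

test_that("normalization invariants hold on random matrices", {
  set.seed(99)
  catalog <- default_lipid_catalog(30, seed = 99)
  for (rep in 1:25) {
    values <- matrix(2^stats::runif(30 * 4, 5, 20), nrow = 30,
                     dimnames = list(catalog, paste0("s", 1:4)))
    m <- intensity_matrix(values)
    expect_silent(validate_state(total_intensity_normalize(m)))
    expect_silent(validate_state(log2_median_normalize(m)))
    # both normalizations commute with row/column reordering
    perm_r <- sample(30)
    perm_c <- sample(4)
    mp <- intensity_matrix(values[perm_r, perm_c])
    expect_equal(
      total_intensity_normalize(mp)$values,
      total_intensity_normalize(m)$values[perm_r, perm_c]
    )
    expect_equal(
      log2_median_normalize(mp)$values,
      log2_median_normalize(m)$values[perm_r, perm_c]
    )
  }
})

test_that("missing values stay missing and are excluded from medians and sums", {
  values <- matrix(c(4, NA, 16, 2, 8, 32), ncol = 2,
                   dimnames = list(c("PG(16:0/18:1)", "PG(16:0/16:0)",
                                     "PE(16:0/18:1)"), c("s1", "s2")))
  m <- intensity_matrix(values)
  tn <- total_intensity_normalize(m)
  expect_true(is.na(tn$values[2, "s1"]))
  expect_equal(unname(tn$values[c(1, 3), "s1"]), c(4, 16) / 20)
  n <- log2_median_normalize(m)
  expect_true(is.na(n$values[2, "s1"]))
  expect_equal(stats::median(n$values[, "s1"], na.rm = TRUE), 0)
})

test_that("reading a wide CSV recovers the matrix and flags bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "lipid,s1,s2",
    "PG(16:0/18:1),100,200",
    "PG(35:1),50,",
    "XX(1:0),10,20"
  ), path)
  expect_warning(m <- read_intensity_table(path, "negative"), "unclassified")
  expect_equal(dim(m), c(3L, 2L))
  expect_identical(m$state, "raw")
  expect_true(is.na(m$values["PG(35:1)", "s2"]))
  # sum-composition row retained with its annotation
  expect_identical(
    m$lipids$resolution[m$lipids$lipid_id == "PG(35:1)"], "sum_composition"
  )
  # unparseable row retained but unclassified
  expect_true(is.na(m$lipids$lipid_class[m$lipids$lipid_id == "XX(1:0)"]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lipid,s1", "PG(16:0/18:1),abc"), bad)
  expect_error(read_intensity_table(bad, "negative"), "non-numeric")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lipid,s1", "PG(16:0/18:1),1", "PG(16:0/18:1),2"), dup)
  expect_error(read_intensity_table(dup, "negative"), "duplicate")
})

test_that("merging modes concatenates disjoint lipid sets over one sample set", {
  neg <- intensity_matrix(
    matrix(1:4, 2, dimnames = list(c("PG(16:0/18:1)", "PE(16:0/16:0)"),
                                   c("s1", "s2")))
  )
  pos <- intensity_matrix(
    matrix(5:8, 2, dimnames = list(c("PC(16:0/18:1)", "TG(16:0/18:1/18:1)"),
                                   c("s1", "s2")))
  )
  merged <- merge_modes(neg, pos)
  expect_equal(nrow(merged$values), 4)
  expect_identical(merged$lipids$mode,
                   c("negative", "negative", "positive", "positive"))
  # one sample missing in pos
  pos_bad <- intensity_matrix(
    matrix(5:6, 2, dimnames = list(c("PC(16:0/18:1)", "TG(16:0/18:1/18:1)"),
                                   "s1"))
  )
  expect_error(merge_modes(neg, pos_bad), "s2")
  # shared lipid ID across modes is an error, not a silent merge
  pos_dup <- intensity_matrix(
    matrix(5:8, 2, dimnames = list(c("PG(16:0/18:1)", "TG(16:0/18:1/18:1)"),
                                   c("s1", "s2"))),
    mode = "positive"
  )
  expect_error(merge_modes(neg, pos_dup), "both modes")
})

test_that("selectors resolve metadata conditions and report bad fields", {
  sim <- make_two_group_sim(n_lipids = 20, seed = 4)
  m <- sim$matrix
  ids <- select_samples(m, list(salinity = 13))
  expect_length(ids, 3)
  expect_error(select_samples(m, list(depth = 1)), "not a metadata column")
  expect_error(select_samples(m, list(salinity = 99)), "salinity")
  expect_error(select_samples(m, c("nope")), "unknown sample")
})
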
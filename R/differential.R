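#' Two-sample Student's t-test
#'
#' Equal-variance (pooled) two-sided t-test, the test used throughout the
#' pairwise lipid comparisons. Degenerate inputs follow explicit
#' conventions: zero pooled variance with equal means gives p = 1; zero
#' pooled variance with unequal means gives p = 0 with a degeneracy
#' warning.
#'
#' @param a,b Numeric replicate vectors (each >= 2 non-missing values).
#' @return List with `statistic` (t), `p_value`, `df`.
#' @export
#' @examples
#' student_t(c(1, 2, 3), c(1, 2, 3))$p_value # 1
student_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) {
      return(list(statistic = 0, p_value = 1, df = df))
    }
    warning("zero pooled variance with unequal means; p set to 0",
            call. = FALSE)
    return(list(statistic = sign(delta) * Inf, p_value = 0, df = df))
  }
  tstat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tstat, p_value = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' Log2 fold change between two groups
#'
#' Inputs are already on the log2 scale, so the fold change is a difference
#' of group means. Under the default `"B_over_A"` convention the value is
#' `mean(b) - mean(a)`: positive means elevated in the second-listed
#' condition (so for a 13% vs 20% NaCl comparison, species elevated at 20%
#' carry positive values).
#'
#' @param a,b Numeric log2-scale vectors.
#' @param convention `"B_over_A"` (default) or `"A_over_B"`.
#' @return A single numeric log2 fold change.
#' @export
log2_fc <- function(a, b, convention = c("B_over_A", "A_over_B")) {
  convention <- match.arg(convention)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  fc <- mean(b) - mean(a)
  if (convention == "A_over_B") fc <- -fc
  fc
}

#' Pairwise differential-abundance table
#'
#' For every lipid, tests group A against group B with Student's t-test and
#' computes the log2 fold change; a lipid is significant when
#' `p < p_threshold` and `|log2FC| > fc_threshold` (the workflow's default
#' criteria are p < 0.05, |log2FC| > 1.5, with a stricter 0.01 / 2.5 pass
#' for the most discriminant species). Lipids with fewer than two
#' replicates in either group are flagged untestable and excluded from
#' counts.
#'
#' @param m An `intensity_matrix` in `"log2_median"` state.
#' @param a,b Sample selectors (see [select_samples()]); must resolve to
#'   disjoint, nonempty sets. A is the reference; positive fold changes are
#'   elevated in B under the default convention.
#' @param p_threshold,fc_threshold Significance / effect-size thresholds.
#' @param convention Fold-change sign convention, see [log2_fc()].
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @param adjust_p Apply Benjamini-Hochberg correction before thresholding
#'   (off by default: the workflow filters on raw p plus effect size).
#' @return A tibble of class `differential_table`, one row per lipid:
#'   `lipid_id`, `lipid_class`, `charge_class`, `mode`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `log2_fc`, `significant`, `direction`
#'   (`"up_in_B"` / `"down_in_B"` / `"none"`), `untestable`. Thresholds,
#'   group definitions and the convention are stored as attributes.
#' @export
differential_table <- function(m, a, b, p_threshold = 0.05,
                               fc_threshold = 1.5,
                               convention = c("B_over_A", "A_over_B"),
                               welch = FALSE, adjust_p = FALSE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "log2_median") {
    stop("differential testing expects a log2_median matrix", call. = FALSE)
  }
  convention <- match.arg(convention)
  ids_a <- select_samples(m, a)
  ids_b <- select_samples(m, b)
  if (length(intersect(ids_a, ids_b)) > 0L) {
    stop("group selectors overlap", call. = FALSE)
  }
  va <- m$values[, ids_a, drop = FALSE]
  vb <- m$values[, ids_b, drop = FALSE]
  n_lip <- nrow(m$values)
  p <- stat <- fc <- rep(NA_real_, n_lip)
  n_a <- rowSums(!is.na(va))
  n_b <- rowSums(!is.na(vb))
  testable <- n_a >= 2L & n_b >= 2L
  for (i in which(testable)) {
    xa <- va[i, ][!is.na(va[i, ])]
    xb <- vb[i, ][!is.na(vb[i, ])]
    if (welch) {
      res <- stats::t.test(xa, xb)
      stat[i] <- unname(res$statistic)
      p[i] <- res$p.value
    } else {
      res <- student_t(xa, xb)
      stat[i] <- res$statistic
      p[i] <- res$p_value
    }
    fc[i] <- log2_fc(xa, xb, convention)
  }
  p_use <- if (adjust_p) stats::p.adjust(p, method = "BH") else p
  significant <- !is.na(p_use) & p_use < p_threshold & abs(fc) > fc_threshold
  up_sign <- if (convention == "B_over_A") 1 else -1
  direction <- rep("none", n_lip)
  direction[significant & sign(fc) == up_sign] <- "up_in_B"
  direction[significant & sign(fc) == -up_sign] <- "down_in_B"
  out <- tibble(
    lipid_id = rownames(m$values),
    lipid_class = m$lipids$lipid_class,
    charge_class = m$lipids$charge_class,
    mode = m$lipids$mode,
    n_a = as.integer(n_a),
    n_b = as.integer(n_b),
    statistic = stat,
    p_value = if (adjust_p) p_use else p,
    log2_fc = fc,
    significant = significant,
    direction = direction,
    untestable = !testable
  )
  structure(
    out,
    class = c("differential_table", class(out)),
    p_threshold = p_threshold,
    fc_threshold = fc_threshold,
    group_a = ids_a,
    group_b = ids_b,
    convention = convention,
    welch = welch,
    adjust_p = adjust_p
  )
}

# accept either a differential_table or any data frame carrying the needed
# columns (so printed differential calls can be tallied directly)
.as_diff_calls <- function(table,
                           needed = c("lipid_class", "significant",
                                      "direction")) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop(
      sprintf("table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      call. = FALSE
    )
  }
  table
}

#' Subclass composition of the differential species
#'
#' Tallies the significant lipids of a comparison by subclass, with
#' percentages of the matching set and a headgroup-charge roll-up (e.g. the
#' anionic share of the species elevated in the second condition).
#'
#' @param table A `differential_table`, or any data frame with columns
#'   `lipid_class`, `significant`, `direction`.
#' @param direction `"all"`, `"up"` (up in B) or `"down"`.
#' @return List with `n` (species matching the filter), `by_class` and
#'   `by_charge` tibbles (`count`, `percent`), where percent =
#'   100 * count / n.
#' @export
subclass_composition <- function(table, direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  calls <- .as_diff_calls(table)
  keep <- calls$significant
  if (direction == "up") keep <- keep & calls$direction == "up_in_B"
  if (direction == "down") keep <- keep & calls$direction == "down_in_B"
  sel <- calls[keep & !is.na(calls$lipid_class), , drop = FALSE]
  n <- nrow(sel)
  if (n == 0L) {
    return(list(
      n = 0L,
      by_class = tibble(lipid_class = character(0), count = integer(0),
                        percent = numeric(0)),
      by_charge = tibble(charge_class = character(0), count = integer(0),
                         percent = numeric(0))
    ))
  }
  by_class <- sel |>
    dplyr::count(.data$lipid_class, name = "count") |>
    dplyr::mutate(percent = 100 * .data$count / n) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$lipid_class)
  charges <- classify_headgroup_charge(sel$lipid_class)
  by_charge <- tibble(charge_class = charges) |>
    dplyr::count(.data$charge_class, name = "count") |>
    dplyr::mutate(percent = 100 * .data$count / n) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$charge_class)
  list(n = n, by_class = by_class, by_charge = by_charge)
}

#' Headline counts and percentages for a comparison
#'
#' @param table A `differential_table` or data frame with `significant` and
#'   `direction` columns.
#' @param detected_total Total number of detected lipids the percentages
#'   refer to (>= number significant).
#' @return List with `n_significant`, `percent_of_detected`
#'   (100 * n_significant / detected_total), `n_up`, `n_down`,
#'   `percent_up` (100 * n_up / n_significant, `NA` when nothing is
#'   significant). Percentages are unrounded; see [round_percent()].
#' @export
summarize_counts <- function(table, detected_total) {
  calls <- .as_diff_calls(table, needed = c("significant", "direction"))
  stopifnot(is.numeric(detected_total), detected_total >= 0)
  n_sig <- sum(calls$significant, na.rm = TRUE)
  if (detected_total < n_sig) {
    stop("detected_total is smaller than the significant count", call. = FALSE)
  }
  n_up <- sum(calls$significant & calls$direction == "up_in_B", na.rm = TRUE)
  n_down <- sum(calls$significant & calls$direction == "down_in_B", na.rm = TRUE)
  list(
    n_significant = n_sig,
    percent_of_detected = if (detected_total > 0) 100 * n_sig / detected_total else NA_real_,
    n_up = n_up,
    n_down = n_down,
    percent_up = if (n_sig > 0) 100 * n_up / n_sig else NA_real_
  )
}

#' Round a percentage the way the report conventions do
#'
#' Approximate ("~") figures are reported to the nearest integer, exact
#' ones to one decimal.
#'
#' @param x Numeric percentage(s).
#' @param style `"approx"` (nearest integer) or `"one_decimal"`.
#' @return Rounded numeric.
#' @export
round_percent <- function(x, style = c("approx", "one_decimal")) {
  style <- match.arg(style)
  if (style == "approx") round(x) else round(x, 1)
}

#' One-way ANOVA screen for the most discriminant lipids
#'
#' Ranks lipids by one-way ANOVA p-value across all condition groups (the
#' screen used to pick the species shown in clustering heatmaps). Ties are
#' broken by descending F statistic, then lexicographic lipid ID. Raw
#' p-values are used.
#'
#' @param m An `intensity_matrix` in `"log2_median"` state.
#' @param labels Group label per sample: a vector of length `ncol`, or the
#'   name of a `sample_meta` column.
#' @param k Number of top lipids to return; `k = 0` gives an empty result,
#'   `k` above the lipid count returns all with a warning.
#' @return A tibble `lipid_id`, `f_statistic`, `p_value`, ordered most
#'   discriminant first.
#' @export
anova_screen <- function(m, labels, k) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (is.character(labels) && length(labels) == 1L &&
      !is.null(m$sample_meta) && labels %in% names(m$sample_meta)) {
    labels <- m$sample_meta[[labels]]
  }
  stopifnot(length(labels) == ncol(m$values))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(labels) < 2L)) stop("every group needs >= 2 samples", call. = FALSE)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  res <- apply(m$values, 1, function(v) {
    ok <- !is.na(v)
    if (length(unique(labels[ok])) < 2L) return(c(NA_real_, NA_real_))
    fit <- stats::oneway.test(v[ok] ~ labels[ok], var.equal = TRUE)
    c(unname(fit$statistic), fit$p.value)
  })
  out <- tibble(
    lipid_id = rownames(m$values),
    f_statistic = unname(res[1, ]),
    p_value = unname(res[2, ])
  )
  out <- out[order(out$p_value, -out$f_statistic, out$lipid_id), ]
  if (k > nrow(out)) {
    warning("k exceeds the number of lipids; returning all", call. = FALSE)
    k <- nrow(out)
  }
  out[seq_len(k), ]
}
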
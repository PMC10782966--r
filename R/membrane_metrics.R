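# shared validation for the abundance-weighted membrane statistics
.check_weights <- function(weights, n) {
  if (n == 0L) stop("empty lipid set", call. = FALSE)
  stopifnot(is.numeric(weights), length(weights) == n)
  if (anyNA(weights)) stop("missing weight", call. = FALSE)
  if (any(weights < 0)) {
    stop(paste(
      "negative abundance weight: weights must be log2 raw intensities",
      "(before median centering), or min-shifted values via the offset",
      "option of membrane_indices()"
    ), call. = FALSE)
  }
  if (sum(weights) == 0) stop("weights sum to zero", call. = FALSE)
  invisible(TRUE)
}

.species_list <- function(species) {
  if (inherits(species, "lipid_species")) return(list(species))
  stopifnot(is.list(species))
  lapply(species, function(sp) {
    if (inherits(sp, "lipid_species")) sp else parse_lipid_name(sp)
  })
}

#' Abundance-weighted double-bond index (DBI)
#'
#' The log2-abundance-weighted mean number of double bonds over a lipid
#' set: `sum(d_i * w_i) / sum(w_i)`, where `d_i` is lipid i's total
#' double-bond count and `w_i` its log2 abundance. A proxy for membrane
#' unsaturation (fluidity). Sum-composition species contribute their
#' composition totals; ambiguous species their primary annotation.
#'
#' @param species List of `lipid_species` (or shorthand names to parse).
#' @param weights Positive log2-abundance weight per species.
#' @return A single numeric DBI.
#' @export
#' @examples
#' double_bond_index(list("PG(14:1/15:1)"), 5) # 2
double_bond_index <- function(species, weights) {
  sps <- .species_list(species)
  .check_weights(weights, length(sps))
  d <- vapply(sps, function(sp) sp$total_double_bonds, numeric(1))
  sum(d * weights) / sum(weights)
}

#' Abundance-weighted mean chain length (MCL)
#'
#' The log2-abundance-weighted mean hydrocarbon chain length:
#' `sum(L_i * w_i) / sum(w_i)` with `L_i` from [chain_summary()] (by
#' default a lipid's total acyl carbons). A proxy for membrane thickness.
#'
#' @inheritParams double_bond_index
#' @param basis Chain-length definition passed to [chain_summary()].
#' @return A single numeric MCL.
#' @export
#' @examples
#' mean_chain_length(list("PG(14:1/15:1)"), 5) # 29
mean_chain_length <- function(species, weights,
                              basis = c("total", "per_chain_mean")) {
  basis <- match.arg(basis)
  sps <- .species_list(species)
  .check_weights(weights, length(sps))
  len <- vapply(sps, function(sp) chain_summary(sp, basis)$chain_length,
                numeric(1))
  sum(len * weights) / sum(weights)
}

#' DBI and MCL of a lipid subset of a matrix
#'
#' Computes both membrane statistics over a stated lipid subset (typically
#' the differential species of a pairwise comparison), weighting each lipid
#' by the mean of its log2 raw intensities across the selected samples.
#' Weights are taken *before* median centering — centering produces
#' negative weights that break the weighted-mean interpretation — so `m`
#' must be in `"raw"` state; `offset = TRUE` instead accepts a
#' `"log2_median"` matrix and min-shifts the centered values to be
#' nonnegative, with a warning.
#'
#' @param m An `intensity_matrix` in `"raw"` state (or `"log2_median"` with
#'   `offset = TRUE`).
#' @param lipid_ids Lipid IDs of the subset (e.g. significant species from a
#'   [differential_table()]).
#' @param samples Optional sample selector; defaults to all samples.
#' @param basis Chain-length definition, see [mean_chain_length()].
#' @param offset Permit min-shifted median-centered weights.
#' @param subset_description Free-text description stored in the result.
#' @return List of class `membrane_indices`: `dbi`, `mcl`, `n_lipids_used`,
#'   `subset_description`.
#' @export
membrane_indices <- function(m, lipid_ids, samples = NULL,
                             basis = c("total", "per_chain_mean"),
                             offset = FALSE,
                             subset_description = "") {
  stopifnot(inherits(m, "intensity_matrix"))
  basis <- match.arg(basis)
  if (m$state == "raw") {
    log2_vals <- log2(m$values)
  } else if (m$state == "log2_median" && offset) {
    warning("using min-shifted median-centered values as weights",
            call. = FALSE)
    log2_vals <- m$values - min(m$values, na.rm = TRUE)
  } else {
    stop("weights require a raw-state matrix (or log2_median with offset = TRUE)",
         call. = FALSE)
  }
  idx <- match(lipid_ids, rownames(m$values))
  if (anyNA(idx)) {
    stop(
      sprintf("unknown lipid ID(s): %s",
              paste(lipid_ids[is.na(idx)], collapse = ", ")),
      call. = FALSE
    )
  }
  if (!is.null(samples)) {
    samples <- select_samples(m, samples)
  } else {
    samples <- colnames(m$values)
  }
  weights <- rowMeans(log2_vals[idx, samples, drop = FALSE], na.rm = TRUE)
  sps <- m$lipids$species[idx]
  if (any(vapply(sps, is.null, logical(1)))) {
    stop("subset contains unparseable lipid names", call. = FALSE)
  }
  structure(
    list(
      dbi = double_bond_index(sps, weights),
      mcl = mean_chain_length(sps, weights, basis),
      n_lipids_used = length(idx),
      subset_description = subset_description
    ),
    class = "membrane_indices"
  )
}

#' @export
print.membrane_indices <- function(x, ...) {
  cat(sprintf(
    "<membrane_indices> DBI %.3f, MCL %.3f over %d lipids%s\n",
    x$dbi, x$mcl, x$n_lipids_used,
    if (nzchar(x$subset_description)) paste0(" (", x$subset_description, ")") else ""
  ))
  invisible(x)
}

#' Per-sample headgroup charge-composition profile
#'
#' Aggregates total-normalized abundances into anionic, zwitterionic and
#' neutral fractions per sample. The default `"core_classes"` basis uses
#' the conventional roll-up — anionic = PG + CL, zwitterionic = PC + PE,
#' neutral = DG + TG + sphingolipids (Cer, HexCer) — and excludes PA
#' entirely; `"all_classes"` includes PA with the anionic fraction.
#' Fractions are renormalized over the included classes so they sum to 1.
#'
#' @param m An `intensity_matrix` in `"total_normalized"` state.
#' @param basis `"core_classes"` (PA excluded) or `"all_classes"`.
#' @return A tibble with `sample_id`, `anionic`, `zwitterionic`, `neutral`
#'   (and the basis as an attribute).
#' @export
charge_profile <- function(m, basis = c("core_classes", "all_classes")) {
  stopifnot(inherits(m, "intensity_matrix"))
  basis <- match.arg(basis)
  if (m$state != "total_normalized") {
    stop("charge profiles are composition summaries: expected total_normalized state",
         call. = FALSE)
  }
  classes <- m$lipids$lipid_class
  include <- !is.na(classes)
  if (basis == "core_classes") include <- include & classes != "PA"
  if (!any(include)) stop("no classifiable lipids in the matrix", call. = FALSE)
  charge <- rep(NA_character_, nrow(m$values))
  charge[include] <- classify_headgroup_charge(classes[include])
  sum_by <- function(chg) {
    rows <- which(!is.na(charge) & charge == chg)
    if (length(rows) == 0L) return(rep(0, ncol(m$values)))
    colSums(m$values[rows, , drop = FALSE], na.rm = TRUE)
  }
  an <- sum_by("anionic")
  zw <- sum_by("zwitterionic")
  ne <- sum_by("neutral")
  total <- an + zw + ne
  if (any(total == 0)) {
    stop(
      sprintf("sample(s) with zero included-class abundance: %s",
              paste(colnames(m$values)[total == 0], collapse = ", ")),
      call. = FALSE
    )
  }
  out <- tibble(
    sample_id = colnames(m$values),
    anionic = unname(an / total),
    zwitterionic = unname(zw / total),
    neutral = unname(ne / total)
  )
  attr(out, "basis") <- basis
  out
}
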
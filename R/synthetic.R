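# Subclass sampling weights for generated catalogs, mirroring the relative
# richness of the 13 shorthand subclasses (9 headgroup classes + lyso forms
# of the diacyl phospholipids) seen in shale-culture lipidomes: anionic PGs
# and neutral glycerolipids are species-rich, PA and sphingolipids sparse.
.CATALOG_CLASS_WEIGHTS <- c(
  PG = 0.20, PE = 0.15, PC = 0.13, PA = 0.05, CL = 0.09,
  DG = 0.14, TG = 0.09, Cer = 0.05, HexCer = 0.05, lyso = 0.05
)

.random_chain <- function(n, sphingoid = FALSE) {
  carbons <- sample(12:22, n, replace = TRUE)
  db <- sample(0:3, n, replace = TRUE, prob = c(0.35, 0.4, 0.2, 0.05))
  if (sphingoid) carbons <- sample(16:20, n, replace = TRUE)
  sprintf("%s%d:%d", if (sphingoid) "d" else "", carbons, db)
}

.random_name <- function() {
  pick <- sample(names(.CATALOG_CLASS_WEIGHTS), 1,
                 prob = .CATALOG_CLASS_WEIGHTS)
  lyso <- pick == "lyso"
  cls <- if (lyso) sample(c("PG", "PE", "PC", "PA"), 1) else pick
  form <- sample(c("full", "sum", "ambiguous"), 1,
                 prob = c(0.82, 0.12, 0.06))
  suffix <- if (stats::runif(1) < 0.15) {
    paste0("_", sample(c("A", "B", "C"), 1))
  } else {
    ""
  }
  comp_for <- function() {
    if (cls == "CL") {
      paste(.random_chain(4), collapse = "/")
    } else if (cls %in% c("DG", "TG")) {
      ch <- .random_chain(3)
      if (cls == "DG") ch[3] <- "0:0"
      paste(ch, collapse = "/")
    } else if (cls %in% c("Cer", "HexCer")) {
      paste(c(.random_chain(1, sphingoid = TRUE), .random_chain(1)),
            collapse = "/")
    } else if (lyso) {
      paste(c(.random_chain(1), "0:0"), collapse = "/")
    } else {
      paste(.random_chain(2), collapse = "/")
    }
  }
  if (form == "sum" && !lyso && !cls %in% c("Cer", "HexCer")) {
    tot_c <- sample(28:44, 1)
    tot_d <- sample(0:4, 1)
    sprintf("%s(%d:%d)%s", cls, tot_c, tot_d, suffix)
  } else if (form == "ambiguous" && !lyso) {
    paste0(sprintf("%s(%s)", cls, comp_for()), suffix, "/",
           sprintf("%s(%s)", cls, comp_for()))
  } else {
    sprintf("%s(%s)%s", cls, comp_for(), suffix)
  }
}

#' Generate a catalog of shorthand lipid names
#'
#' Produces `n` unique, parseable species names spanning all nine headgroup
#' classes plus lyso, sum-composition, ambiguous and isomer-suffixed forms.
#' The reference corpus of observed shale-bacterium species
#' ([reference_species_names()]) is always included (when `n` allows);
#' remaining names are drawn from the shorthand grammar with subclass
#' weights mirroring shale-culture lipidomes.
#'
#' @param n Number of species (>= 13; default 194, the size of a typical
#'   two-mode shale-culture lipidome).
#' @param seed Optional integer seed; the same seed gives the same catalog.
#' @return Character vector of `n` unique shorthand names.
#' @export
default_lipid_catalog <- function(n = 194, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 13)
  if (!is.null(seed)) set.seed(seed)
  corpus <- reference_species_names()
  names <- if (n >= length(corpus)) corpus else character(0)
  guard <- 0L
  while (length(names) < n) {
    cand <- .random_name()
    if (!cand %in% names) {
      # keep only names the parser accepts (the generator and parser share
      # the grammar, so rejects indicate a generator bug)
      names <- c(names, cand)
    }
    guard <- guard + 1L
    if (guard > 100L * n) stop("catalog generation failed to converge", call. = FALSE)
  }
  names
}

#' Full-factorial study design for the chemostat/biofilm experiments
#'
#' The default design mirrors the isolate experiments: planktonic growth
#' at salinity 7/13/20 percent NaCl crossed with hydraulic retention times
#' 19.2/24/48 h (9 conditions), plus biofilm growth at the three salinities
#' (incubated 48 h). With 3 replicates this gives 27 planktonic and 9
#' biofilm samples.
#'
#' @param salinities Percent NaCl levels.
#' @param hrts Hydraulic retention times in hours (planktonic conditions).
#' @param biofilm Include the biofilm arm.
#' @param n_rep Replicates per condition.
#' @return A tibble with `sample_id`, `salinity`, `hrt`, `growth_mode`,
#'   `replicate`.
#' @export
study_design <- function(salinities = c(7, 13, 20),
                         hrts = c(19.2, 24, 48),
                         biofilm = TRUE, n_rep = 3) {
  plank <- expand.grid(salinity = salinities, hrt = hrts,
                       growth_mode = "planktonic",
                       replicate = seq_len(n_rep),
                       stringsAsFactors = FALSE)
  design <- plank
  if (biofilm) {
    bf <- expand.grid(salinity = salinities, hrt = max(hrts),
                      growth_mode = "biofilm",
                      replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
    design <- rbind(plank, bf)
  }
  design$sample_id <- sprintf(
    "S%g_H%g_%s_R%d", design$salinity, design$hrt,
    ifelse(design$growth_mode == "planktonic", "PEL", "BF"),
    design$replicate
  )
  as_tibble(design[, c("sample_id", "salinity", "hrt", "growth_mode",
                       "replicate")])
}

#' Simulate a lipidome intensity matrix with planted effects
#'
#' Generates raw LC-MS-like peak intensities under a log-normal model:
#' `intensity = 2^(baseline_i + delta * I(condition) + N(0, sigma))`, with
#' per-lipid baselines drawn uniformly from a realistic log2 dynamic range.
#' Planted effects are applied on the log2 scale, so ground-truth fold
#' changes are exact. Missing values are inserted completely at random at
#' `missing_rate`, but never to the point of wiping out an entire
#' (lipid, condition) group.
#'
#' @param catalog Character vector of lipid names ([default_lipid_catalog()]
#'   by default via `n_lipids`).
#' @param design Sample design tibble (see [study_design()]); any data frame
#'   with `sample_id` plus condition columns works.
#' @param n_lipids Catalog size when `catalog` is `NULL`.
#' @param baseline_range Range of per-lipid baseline log2 means (default
#'   `c(10, 25)`, typical LC-MS peak-intensity scales).
#' @param sigma Within-group log2 standard deviation (default 0.5).
#' @param effects List of planted effects; each is a list with either
#'   `lipids` (IDs) or `class` (subclass token, optionally with `n_lipids`
#'   to plant on a random subset), a `selector` (named condition list, see
#'   [select_samples()]) identifying the samples that receive the shift,
#'   and `delta` (log2 shift).
#' @param missing_rate Fraction of cells set missing (default 0).
#' @param seed Optional integer seed; fixed seed gives a bit-identical
#'   matrix.
#' @return List with `matrix` (a raw-state [intensity_matrix()]) and
#'   `truth` (list: `planted` tibble of `lipid_id`, `delta`,
#'   `selector_description`; `seed`; `sigma`).
#' @export
simulate_lipidome <- function(catalog = NULL, design = study_design(),
                              n_lipids = 194,
                              baseline_range = c(10, 25), sigma = 0.5,
                              effects = list(), missing_rate = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(catalog)) catalog <- default_lipid_catalog(n_lipids)
  stopifnot(!anyDuplicated(catalog))
  design <- as_tibble(design)
  stopifnot("sample_id" %in% names(design))
  n_lip <- length(catalog)
  n_smp <- nrow(design)

  baseline <- stats::runif(n_lip, baseline_range[1], baseline_range[2])
  log2_mu <- matrix(baseline, n_lip, n_smp,
                    dimnames = list(catalog, design$sample_id))

  # a bare matrix is enough to resolve selectors against the design
  shell <- intensity_matrix(
    matrix(1, n_lip, n_smp, dimnames = dimnames(log2_mu)),
    mode = "negative", sample_meta = design, state = "raw"
  )
  planted <- list()
  for (eff in effects) {
    stopifnot(is.list(eff), !is.null(eff$delta), !is.null(eff$selector))
    if (!is.null(eff$lipids)) {
      ids <- eff$lipids
      if (!all(ids %in% catalog)) {
        stop(
          sprintf("planted effect names unknown lipid(s): %s",
                  paste(setdiff(ids, catalog), collapse = ", ")),
          call. = FALSE
        )
      }
    } else if (!is.null(eff$class)) {
      ann <- suppressWarnings(annotate_lipids(catalog))
      ids <- ann$lipid_id[!is.na(ann$lipid_class) &
                            ann$lipid_class == eff$class]
      if (length(ids) == 0L) {
        stop(sprintf("planted effect matches no lipid of class %s", eff$class),
             call. = FALSE)
      }
      if (!is.null(eff$n_lipids) && eff$n_lipids < length(ids)) {
        ids <- sample(ids, eff$n_lipids)
      }
    } else {
      stop("each effect needs `lipids` or `class`", call. = FALSE)
    }
    target_samples <- select_samples(shell, eff$selector)
    log2_mu[ids, target_samples] <- log2_mu[ids, target_samples] + eff$delta
    planted[[length(planted) + 1L]] <- tibble(
      lipid_id = ids,
      delta = eff$delta,
      selector_description = paste(
        names(eff$selector),
        vapply(eff$selector, function(v) paste(v, collapse = "/"), character(1)),
        sep = "=", collapse = ", "
      )
    )
  }

  values <- 2^(log2_mu + matrix(stats::rnorm(n_lip * n_smp, sd = sigma),
                                n_lip, n_smp))

  if (missing_rate > 0) {
    stopifnot(missing_rate < 1)
    group <- do.call(
      paste,
      c(design[setdiff(names(design), c("sample_id", "replicate"))], sep = "|")
    )
    for (g in unique(group)) {
      cols <- which(group == g)
      drop <- matrix(stats::runif(n_lip * length(cols)) < missing_rate,
                     n_lip, length(cols))
      # keep at least one observed replicate per (lipid, condition)
      all_gone <- rowSums(!drop) == 0
      if (any(all_gone)) {
        keep_col <- sample(length(cols), sum(all_gone), replace = TRUE)
        drop[cbind(which(all_gone), keep_col)] <- FALSE
      }
      block <- values[, cols, drop = FALSE]
      block[drop] <- NA_real_
      values[, cols] <- block
    }
  }

  m <- intensity_matrix(values, mode = NULL, sample_meta = design,
                        state = "raw")
  truth <- list(
    planted = if (length(planted) > 0L) dplyr::bind_rows(planted)
              else tibble(lipid_id = character(0), delta = numeric(0),
                          selector_description = character(0)),
    seed = seed,
    sigma = sigma
  )
  list(matrix = m, truth = truth)
}

#' Write a simulated lipidome to disk
#'
#' Writes the mode-split wide intensity tables (`negative.csv`,
#' `positive.csv`), the sample metadata (`metadata.csv`) and the planted
#' ground truth (`truth.json`) into a directory.
#'
#' @param sim Result of [simulate_lipidome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(is.list(sim), inherits(sim$matrix, "intensity_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- sim$matrix
  paths <- character(0)
  for (md in unique(m$lipids$mode)) {
    rows <- m$lipids$mode == md
    df <- data.frame(lipid = rownames(m$values)[rows],
                     m$values[rows, , drop = FALSE],
                     check.names = FALSE)
    path <- file.path(dir, paste0(md, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(m$sample_meta, meta_path, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted = sim$truth$planted,
         seed = sim$truth$seed, sigma = sim$truth$sigma),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(paths, meta_path, truth_path))
}
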
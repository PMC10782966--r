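#' Construct an intensity matrix
#'
#' The central container of the pipeline: a lipids-by-samples grid of peak
#' intensities with per-lipid ionization mode, per-sample condition
#' metadata, species annotations derived from the shorthand names, and a
#' normalization state (`"raw"`, `"total_normalized"` or `"log2_median"`).
#'
#' @param values Numeric matrix, rows = lipids (rownames = shorthand names,
#'   unique), columns = samples (colnames = sample IDs, unique). Missing
#'   measurements are `NA`, never zero.
#' @param mode Per-lipid ionization mode: a character vector (`"negative"` /
#'   `"positive"`) of length `nrow(values)`, a single value recycled, or
#'   `NULL` to infer each lipid's mode from its class (PG/PE/PA/CL negative;
#'   PC/DG/TG/Cer/HexCer positive).
#' @param sample_meta Optional data frame with a `sample_id` column matching
#'   `colnames(values)` and condition columns (typically `salinity`, `hrt`,
#'   `growth_mode`, `replicate`, `timepoint`).
#' @param state Normalization state of `values`.
#' @return An object of class `intensity_matrix` with fields `values`,
#'   `lipids` (annotation tibble, includes `mode`), `sample_meta`, `state`.
#' @export
intensity_matrix <- function(values, mode = NULL, sample_meta = NULL,
                             state = c("raw", "total_normalized", "log2_median")) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs lipid rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop(
      sprintf("duplicate lipid IDs: %s",
              paste(unique(rownames(values)[duplicated(rownames(values))]),
                    collapse = ", ")),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  if (state == "raw" && any(values < 0, na.rm = TRUE)) {
    stop("raw intensities must be >= 0", call. = FALSE)
  }
  lipids <- annotate_lipids(rownames(values))
  if (is.null(mode)) {
    if (anyNA(lipids$lipid_class)) {
      stop("cannot infer ionization mode for unparseable names; pass `mode`",
           call. = FALSE)
    }
    mode <- unname(.MODE_MAP[lipids$lipid_class])
  }
  if (length(mode) == 1L) mode <- rep(mode, nrow(values))
  stopifnot(length(mode) == nrow(values), all(mode %in% c("negative", "positive")))
  lipids$mode <- mode
  if (!is.null(sample_meta)) {
    sample_meta <- as_tibble(sample_meta)
    if (!"sample_id" %in% names(sample_meta)) {
      stop("`sample_meta` needs a sample_id column", call. = FALSE)
    }
    missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
    if (length(missing_meta) > 0L) {
      stop(
        sprintf("samples without metadata: %s",
                paste(missing_meta, collapse = ", ")),
        call. = FALSE
      )
    }
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  }
  structure(
    list(values = values, lipids = lipids, sample_meta = sample_meta,
         state = state),
    class = "intensity_matrix"
  )
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf(
    "<intensity_matrix> %d lipids x %d samples (%s)\n  modes: %s\n",
    nrow(x$values), ncol(x$values), x$state,
    paste(sprintf("%s=%d", names(table(x$lipids$mode)), table(x$lipids$mode)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Read a wide peak-intensity table
#'
#' Expects a header row of sample IDs and a first column of shorthand lipid
#' names; cells are peak intensities. Empty cells and `NA` are recorded as
#' missing (not zero). All names are validated through the parser; rows
#' whose names fail to parse are retained with a warning and excluded from
#' class-based operations.
#'
#' @param path Path to a CSV (or TSV, `sep = "\t"`) file.
#' @param mode Ionization mode of this table: `"negative"` or `"positive"`.
#' @param sample_meta Optional sample metadata (see [intensity_matrix()]).
#' @param sep Field separator.
#' @return An `intensity_matrix` in `"raw"` state.
#' @export
read_intensity_table <- function(path, mode = c("negative", "positive"),
                                 sample_meta = NULL, sep = ",") {
  mode <- match.arg(mode)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop("table needs a name column and >= 1 sample", call. = FALSE)
  lipid_names <- trimws(raw[[1]])
  if (anyDuplicated(lipid_names)) {
    stop(
      sprintf("duplicate lipid names in %s: %s", path,
              paste(unique(lipid_names[duplicated(lipid_names)]), collapse = ", ")),
      call. = FALSE
    )
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == ""] <- NA_character_
  values <- suppressWarnings(
    matrix(as.numeric(cells), nrow = nrow(cells),
           dimnames = list(lipid_names, colnames(cells)))
  )
  bad <- which(is.na(values) & !is.na(cells) &
                 toupper(trimws(cells)) != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(
      sprintf(
        "non-numeric cell(s): %s",
        paste(sprintf("[%s, %s] = %s", rownames(values)[bad[, 1]],
                      colnames(values)[bad[, 2]], cells[bad]),
              collapse = "; ")
      ),
      call. = FALSE
    )
  }
  intensity_matrix(values, mode = mode, sample_meta = sample_meta, state = "raw")
}

#' Read a sample-metadata table
#'
#' @param path CSV file keyed by `sample_id`, with condition columns such as
#'   `salinity` (percent NaCl), `hrt` (hours), `growth_mode`
#'   (`"planktonic"` / `"biofilm"`), `replicate`, `timepoint`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata needs a sample_id column", call. = FALSE)
  }
  as_tibble(meta)
}

# rows of the matrix belonging to one ionization-mode block
.mode_blocks <- function(m) split(seq_len(nrow(m$values)), m$lipids$mode)

#' Total-intensity normalization
#'
#' Divides each value by the total intensity of its (sample, ionization
#' mode) block, so that within every sample each mode's intensities sum to
#' one — the composition scale used for class relative-abundance and
#' charge-profile summaries. The two modes are normalized independently.
#' Missing values contribute zero to the block sum and stay missing.
#'
#' @param m An `intensity_matrix` in `"raw"` state.
#' @return An `intensity_matrix` in `"total_normalized"` state.
#' @export
total_intensity_normalize <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "raw") stop("expected a raw-state matrix", call. = FALSE)
  values <- m$values
  for (block in .mode_blocks(m)) {
    sums <- colSums(values[block, , drop = FALSE], na.rm = TRUE)
    zero <- sums == 0
    if (any(zero)) {
      stop(
        sprintf("all-zero %s-mode block for sample(s): %s",
                m$lipids$mode[block[1]],
                paste(colnames(values)[zero], collapse = ", ")),
        call. = FALSE
      )
    }
    values[block, ] <- sweep(values[block, , drop = FALSE], 2, sums, "/")
  }
  out <- m
  out$values <- values
  out$state <- "total_normalized"
  out
}

#' Log2 transform and median scaling
#'
#' Log2-transforms intensities, then centers each sample by subtracting its
#' median log2 value (equivalently: divides by the median intensity before
#' the log). The two ionization modes are normalized separately, so the
#' median is taken within each (sample, mode) block; for a single-mode
#' matrix every sample's median becomes exactly zero. Nonpositive
#' intensities are an error — no silent pseudocount is applied (set
#' `zero_substitute = TRUE` to replace zeros by half the smallest positive
#' value in the matrix first).
#'
#' @param m An `intensity_matrix` in `"raw"` state.
#' @param zero_substitute Replace exact zeros by min-positive/2 before the
#'   transform. Off by default.
#' @return An `intensity_matrix` in `"log2_median"` state.
#' @export
log2_median_normalize <- function(m, zero_substitute = FALSE) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$state != "raw") stop("expected a raw-state matrix", call. = FALSE)
  values <- m$values
  if (zero_substitute && any(values == 0, na.rm = TRUE)) {
    half_min <- min(values[values > 0], na.rm = TRUE) / 2
    values[!is.na(values) & values == 0] <- half_min
  }
  bad <- which(values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(
      sprintf("nonpositive intensity at: %s",
              paste(sprintf("[%s, %s]", rownames(values)[bad[, 1]],
                            colnames(values)[bad[, 2]]), collapse = "; ")),
      call. = FALSE
    )
  }
  values <- log2(values)
  for (block in .mode_blocks(m)) {
    med <- apply(values[block, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    values[block, ] <- sweep(values[block, , drop = FALSE], 2, med, "-")
  }
  out <- m
  out$values <- values
  out$state <- "log2_median"
  out
}

#' Merge negative- and positive-mode matrices
#'
#' Row-concatenates two same-state matrices over an identical sample set,
#' preserving each lipid's ionization mode. A lipid ID present in both
#' inputs is an error: the workflow has no rule for reconciling a species
#' detected in both modes.
#'
#' @param neg,pos `intensity_matrix` objects in the same state, with
#'   identical sample sets and disjoint lipid IDs.
#' @return A merged `intensity_matrix`.
#' @export
merge_modes <- function(neg, pos) {
  stopifnot(inherits(neg, "intensity_matrix"), inherits(pos, "intensity_matrix"))
  if (neg$state != pos$state) {
    stop("matrices are in different normalization states", call. = FALSE)
  }
  sdiff <- c(setdiff(colnames(neg$values), colnames(pos$values)),
             setdiff(colnames(pos$values), colnames(neg$values)))
  if (length(sdiff) > 0L) {
    stop(
      sprintf("sample sets differ: %s", paste(sdiff, collapse = ", ")),
      call. = FALSE
    )
  }
  shared <- intersect(rownames(neg$values), rownames(pos$values))
  if (length(shared) > 0L) {
    stop(
      sprintf("lipid ID(s) present in both modes: %s",
              paste(shared, collapse = ", ")),
      call. = FALSE
    )
  }
  values <- rbind(neg$values, pos$values[, colnames(neg$values), drop = FALSE])
  meta <- neg$sample_meta
  out <- intensity_matrix(
    values,
    mode = c(neg$lipids$mode, pos$lipids$mode),
    sample_meta = meta,
    state = neg$state
  )
  out
}

#' Check the invariant of a matrix's declared normalization state
#'
#' `total_normalized`: every (sample, mode) block sums to 1;
#' `log2_median`: every (sample, mode) block has median 0; `raw`: values
#' nonnegative. Returns `TRUE` invisibly or throws.
#'
#' @param m An `intensity_matrix`.
#' @param tol Numerical tolerance.
#' @export
validate_state <- function(m, tol = 1e-9) {
  stopifnot(inherits(m, "intensity_matrix"))
  for (block in .mode_blocks(m)) {
    v <- m$values[block, , drop = FALSE]
    if (m$state == "total_normalized") {
      sums <- colSums(v, na.rm = TRUE)
      if (any(abs(sums - 1) > tol)) stop("block sums differ from 1", call. = FALSE)
    } else if (m$state == "log2_median") {
      med <- apply(v, 2, stats::median, na.rm = TRUE)
      if (any(abs(med) > tol)) stop("block medians differ from 0", call. = FALSE)
    } else if (any(v < 0, na.rm = TRUE)) {
      stop("negative raw intensity", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Resolve a sample selector against the matrix metadata
#'
#' A selector is either a character vector of sample IDs, a logical vector
#' over samples, or a named list of metadata conditions, e.g.
#' `list(salinity = 13, growth_mode = "planktonic", hrt = 24)` — each named
#' field must be a metadata column and each value must match at least one
#' sample.
#'
#' @param m An `intensity_matrix` with `sample_meta` (for list selectors).
#' @param selector See description.
#' @return Character vector of sample IDs.
#' @export
select_samples <- function(m, selector) {
  stopifnot(inherits(m, "intensity_matrix"))
  ids <- colnames(m$values)
  if (is.logical(selector)) {
    stopifnot(length(selector) == length(ids))
    return(ids[selector])
  }
  if (is.character(selector)) {
    unknown <- setdiff(selector, ids)
    if (length(unknown) > 0L) {
      stop(
        sprintf("unknown sample ID(s): %s", paste(unknown, collapse = ", ")),
        call. = FALSE
      )
    }
    return(selector)
  }
  if (!is.list(selector) || is.null(names(selector)) ||
      any(!nzchar(names(selector)))) {
    stop("selector must be sample IDs, a logical vector, or a named list",
         call. = FALSE)
  }
  if (is.null(m$sample_meta)) {
    stop("matrix has no sample metadata to select on", call. = FALSE)
  }
  keep <- rep(TRUE, length(ids))
  for (field in names(selector)) {
    if (!field %in% names(m$sample_meta)) {
      stop(sprintf("selector field %s is not a metadata column",
                   dQuote(field, FALSE)), call. = FALSE)
    }
    hit <- m$sample_meta[[field]] %in% selector[[field]]
    if (!any(hit)) {
      stop(
        sprintf("selector field %s: no sample has value %s",
                dQuote(field, FALSE),
                paste(selector[[field]], collapse = "/")),
        call. = FALSE
      )
    }
    keep <- keep & hit
  }
  if (!any(keep)) stop("selector matches no sample", call. = FALSE)
  ids[keep]
}

# subset a matrix to given lipid ids and/or sample ids, keeping metadata
subset_matrix <- function(m, lipids = NULL, samples = NULL) {
  stopifnot(inherits(m, "intensity_matrix"))
  values <- m$values
  mode <- m$lipids$mode
  if (!is.null(lipids)) {
    idx <- match(lipids, rownames(values))
    if (anyNA(idx)) stop("unknown lipid ID(s)", call. = FALSE)
    values <- values[idx, , drop = FALSE]
    mode <- mode[idx]
  }
  if (!is.null(samples)) {
    values <- values[, match(samples, colnames(values)), drop = FALSE]
  }
  meta <- m$sample_meta
  if (!is.null(meta)) meta <- meta[match(colnames(values), meta$sample_id), ]
  out <- intensity_matrix(values, mode = mode, sample_meta = meta,
                          state = m$state)
  out
}
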
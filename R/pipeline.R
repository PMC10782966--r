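#' Run the full lipidomics analysis from a configuration
#'
#' Orchestrates the whole workflow: input (or simulation), both
#' normalizations, the configured pairwise differential comparisons with
#' membrane indices, per-sample charge profiles, Ward.D2 clustering, and
#' (optionally) the MCCV random-forest biomarker procedure. Every output is
#' a plain-text artifact (CSV / JSON / Newick) plus a provenance record,
#' and the run is deterministic given the configured seeds.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' simulate:            # either this block ...
#'   n_lipids: 194
#'   sigma: 0.5
#'   seed: 1
#' input:               # ... or this one
#'   negative: neg.csv
#'   positive: pos.csv
#'   metadata: meta.csv
#' comparisons:
#'   - name: salinity_13_vs_20
#'     a: {salinity: 13, growth_mode: planktonic, hrt: 24}
#'     b: {salinity: 20, growth_mode: planktonic, hrt: 24}
#'     p_threshold: 0.05
#'     fc_threshold: 1.5
#' biomarker:           # optional
#'   labels: growth_mode
#'   panel_size: 15
#'   rounds: 100
#'   seed: 7
#' output_dir: out/
#' }
#'
#' All comparison selectors are validated against the metadata before any
#' computation; an unresolvable selector aborts the run up front.
#'
#' @param config Path to a YAML file, or a nested list as above.
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a named list of written file paths (the manifest).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NULL
    stopifnot(is.list(config))
  }
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  input_files <- character(0)
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim <- simulate_lipidome(
      n_lipids = sim_cfg$n_lipids %||% 194,
      design = if (!is.null(sim_cfg$design)) as_tibble(sim_cfg$design) else study_design(),
      sigma = sim_cfg$sigma %||% 0.5,
      effects = sim_cfg$effects %||% list(),
      missing_rate = sim_cfg$missing_rate %||% 0,
      seed = sim_cfg$seed
    )
    raw <- sim$matrix
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
      list(planted = sim$truth$planted, seed = sim$truth$seed,
           sigma = sim$truth$sigma),
      truth_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else if (!is.null(config$input)) {
    meta <- read_sample_metadata(config$input$metadata)
    neg <- read_intensity_table(config$input$negative, "negative", meta)
    pos <- read_intensity_table(config$input$positive, "positive", meta)
    raw <- merge_modes(neg, pos)
    input_files <- unlist(config$input)
  } else {
    stop("config needs a `simulate` or `input` block", call. = FALSE)
  }

  comparisons <- config$comparisons %||% list()
  for (cmp in comparisons) {
    if (is.null(cmp$name)) stop("every comparison needs a name", call. = FALSE)
    # resolve selectors before any computation
    select_samples(raw, cmp$a)
    select_samples(raw, cmp$b)
    if (!is.null(cmp$p_threshold) && cmp$p_threshold <= 0) {
      stop("p_threshold must be positive", call. = FALSE)
    }
    if (!is.null(cmp$fc_threshold) && cmp$fc_threshold <= 0) {
      stop("fc_threshold must be positive", call. = FALSE)
    }
  }

  manifest <- list()
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[lipidshift] ", fmt), ...))
  }

  log_stage("normalizing %d lipids x %d samples", nrow(raw$values),
            ncol(raw$values))
  normed <- log2_median_normalize(raw)
  composition <- total_intensity_normalize(raw)

  for (cmp in comparisons) {
    log_stage("comparison %s", cmp$name)
    tbl <- differential_table(
      normed, a = cmp$a, b = cmp$b,
      p_threshold = cmp$p_threshold %||% 0.05,
      fc_threshold = cmp$fc_threshold %||% 1.5
    )
    diff_path <- file.path(out_dir, sprintf("differential_%s.csv", cmp$name))
    export <- as.data.frame(tbl)
    export$neg_log10_p <- -log10(export$p_value)
    utils::write.csv(export, diff_path, row.names = FALSE, na = "")
    manifest[[sprintf("differential_%s", cmp$name)]] <- diff_path

    sig <- tbl$lipid_id[tbl$significant]
    idx_path <- file.path(out_dir, sprintf("indices_%s.json", cmp$name))
    if (length(sig) > 0L) {
      idx <- membrane_indices(
        raw, sig,
        samples = c(attr(tbl, "group_a"), attr(tbl, "group_b")),
        subset_description = sprintf("differential lipids, %s", cmp$name)
      )
      jsonlite::write_json(
        list(dbi = idx$dbi, mcl = idx$mcl, n = idx$n_lipids_used,
             subset = idx$subset_description),
        idx_path, auto_unbox = TRUE, digits = NA
      )
    } else {
      jsonlite::write_json(
        list(dbi = NULL, mcl = NULL, n = 0,
             subset = sprintf("differential lipids, %s (none significant)",
                              cmp$name)),
        idx_path, auto_unbox = TRUE, digits = NA, null = "null"
      )
    }
    manifest[[sprintf("indices_%s", cmp$name)]] <- idx_path
  }

  profile <- charge_profile(composition)
  charge_path <- file.path(out_dir, "charge_profile.csv")
  utils::write.csv(as.data.frame(profile), charge_path, row.names = FALSE)
  manifest$charge_profile <- charge_path

  if (ncol(raw$values) >= 2L) {
    tree_path <- file.path(out_dir, "dendrogram.nwk")
    cluster_newick(ward_cluster(normed), tree_path)
    manifest$dendrogram <- tree_path
  }

  if (!is.null(config$biomarker)) {
    bm_cfg <- config$biomarker
    log_stage("biomarker MCCV (%s rounds)", bm_cfg$rounds %||% 100)
    labels_field <- bm_cfg$labels %||% "growth_mode"
    report <- rf_biomarker_mccv(
      normed, labels_field,
      panel_sizes = bm_cfg$panel_sizes %||% c(3, 5, 10, 15, 25, 50),
      n_rounds = bm_cfg$rounds %||% 100,
      panel_size = bm_cfg$panel_size %||% 15,
      seed = bm_cfg$seed
    )
    bm_path <- file.path(out_dir, "biomarker.json")
    jsonlite::write_json(
      list(
        ranking = report$ranking,
        panel_auc = report$panel_auc,
        accuracy = report$accuracy,
        selected_panel = report$selected_panel,
        panel_size = report$panel_size,
        n_rounds = report$n_rounds,
        seed = report$seed,
        hyperparameters = report$hyperparameters
      ),
      bm_path, auto_unbox = TRUE, digits = NA, null = "null"
    )
    manifest$biomarker <- bm_path
  }

  prov <- list(
    package = "lipidshift",
    version = as.character(utils::packageVersion("lipidshift")),
    config = config,
    config_file = config_path,
    input_md5 = if (length(input_files) > 0L)
      as.list(tools::md5sum(input_files)) else NULL
  )
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$provenance <- prov_path

  invisible(manifest)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
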
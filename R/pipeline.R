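#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' screening constants as defaults: correlation cutoff 0.9 and variance
#' cutoff 1e-5 for feature selection, activity cutoff at 2 standard
#' deviations of the compound distance distribution, saturation cutoff 0.2
#' with self-calibrated focus cutoff for image QC, and control labels
#' "DMSO 0.1%" / "staurosporine 0.3 uM".
#'
#' @param dialect Feature-table CSV dialect (see [read_feature_table()]);
#'   validated immediately.
#' @param qc Run image QC? Set `FALSE` for tables without QC metric columns.
#' @param sat_max,focus_min Image QC thresholds (see [qc_filter_images()]).
#' @param corr_threshold,var_threshold Feature selection thresholds.
#' @param variance_prop Proportion of variance retained by the PC model.
#' @param k_sd Activity cutoff multiplier.
#' @param theta_mode `"2d"` (plane angle, the default) or `"kd"`
#'   (full-dimensional angle).
#' @param top_n Hit-list length (default all pairs).
#' @param exclude Optional manual exclusion list for [build_hit_list()].
#' @param negctrl_label,posctrl_label Descriptive control labels recorded in
#'   the manifest.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed feeds [simulate_screen()] when used).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dialect = "generic",
                            qc = TRUE,
                            sat_max = 0.2,
                            focus_min = NULL,
                            corr_threshold = 0.9,
                            var_threshold = 1e-5,
                            variance_prop = 0.5,
                            k_sd = 2,
                            theta_mode = c("2d", "kd"),
                            top_n = Inf,
                            exclude = NULL,
                            negctrl_label = "DMSO 0.1%",
                            posctrl_label = "staurosporine 0.3 uM",
                            seed = 1L) {
  resolve_dialect(dialect)  # fail before any computation
  theta_mode <- match.arg(theta_mode)
  if (!is.numeric(variance_prop) || variance_prop <= 0 || variance_prop > 1)
    abort("variance_prop must be in (0, 1]", class = "thetascreen_config_error")
  if (!is.numeric(k_sd) || k_sd <= 0)
    abort("k_sd must be > 0", class = "thetascreen_config_error")
  structure(list(dialect = dialect, qc = qc, sat_max = sat_max,
                 focus_min = focus_min, corr_threshold = corr_threshold,
                 var_threshold = var_threshold, variance_prop = variance_prop,
                 k_sd = k_sd, theta_mode = theta_mode, top_n = top_n,
                 exclude = exclude, negctrl_label = negctrl_label,
                 posctrl_label = posctrl_label, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = c("thetascreen_pipeline_error", "thetascreen_stage_error"),
          stage = stage)
  })
}

#' Run the end-to-end screen analysis
#'
#' Chains ingest (QC filter, image- and well-median aggregation, plate-map
#' join), preprocessing (feature selection, plate-wise DMSO normalization),
#' phenotype-space construction (PCA, control centering, activity calls,
#' multivariate Z'), and divergence scoring (theta, delta-theta, rank
#' product, hit list). Every intermediate table is returned and, when
#' `outdir` is given, written as CSV together with a JSON manifest of the
#' configuration, stage row counts and output-file content hashes.
#' Re-running with identical inputs and configuration reproduces identical
#' outputs byte for byte.
#'
#' @param x A `theta_screen` from [generate_screen()], a cell-level feature
#'   tibble, or a path to a feature CSV.
#' @param layout Plate map (tibble or CSV path); taken from `x` when `x` is
#'   a `theta_screen`.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for the CSV artifacts and
#'   `manifest.json`.
#' @return A `theta_run` list: `images`, `wells`, `normalized`, `pca`,
#'   `centered`, `activity`, `zprime`, `theta`, `deltas`, `ranked`, `hits`,
#'   `manifest`.
#' @export
run_pipeline <- function(x, layout = NULL, config = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(x, "theta_screen")) {
    layout <- x$layout
    cells <- x$cells
  } else if (is.character(x)) {
    cells <- stage_run("ingest", read_feature_table(x, config$dialect))
  } else {
    cells <- x
  }
  if (is.character(layout))
    layout <- stage_run("ingest", read_plate_layout(layout))
  if (is.null(layout))
    abort("run_pipeline needs a plate map", class = "thetascreen_config_error")
  stage_run("ingest", validate_layout(cells, layout))

  counts <- list(cells = nrow(cells))
  qc_rep <- tibble::tibble()
  if (isTRUE(config$qc)) {
    cells <- stage_run("qc", qc_filter_images(cells, layout,
                                              sat_max = config$sat_max,
                                              focus_min = config$focus_min))
    qc_rep <- qc_report(cells)
    counts$cells_after_qc <- nrow(cells)
  }
  images <- stage_run("aggregate", aggregate_to_image_median(cells))
  wells <- stage_run("aggregate", aggregate_to_well(images))
  counts$images <- nrow(images)
  counts$wells <- nrow(wells)

  wells_sel <- stage_run("select_features",
                         select_features(wells, layout,
                                         corr_threshold = config$corr_threshold,
                                         var_threshold = config$var_threshold))
  sel_rep <- selection_report(wells_sel)
  counts$features_retained <- length(sel_rep$retained)

  normalized <- stage_run("normalize", normalize_to_dmso(wells_sel, layout))
  nconst <- norm_constants(normalized)

  pca <- stage_run("phenospace", fit_pca(normalized, config$variance_prop))
  centered <- stage_run("phenospace", project_and_center(pca, normalized))
  counts$pc_retained <- pca$k

  activity <- stage_run("activity", call_activity(centered, k_sd = config$k_sd))
  zp <- stage_run("zprime", multivariate_zprime(normalized))
  counts$n_active_calls <- sum(activity$active)

  theta <- stage_run("tccs", compute_theta(centered, activity = activity))
  deltas <- stage_run("tccs", if (config$theta_mode == "kd")
    delta_theta_kd(centered, activity) else delta_theta(theta))
  ranked <- stage_run("rank", rank_product(deltas))
  hits <- stage_run("rank", build_hit_list(ranked, activity = activity,
                                           top_n = config$top_n,
                                           exclude = config$exclude))
  counts$n_ranked_pairs <- nrow(ranked)
  counts$n_hits <- nrow(hits)

  run <- structure(list(images = images, wells = wells,
                        normalized = normalized, pca = pca,
                        centered = centered, activity = activity,
                        zprime = zp, theta = theta, deltas = deltas,
                        ranked = ranked, hits = hits,
                        qc_report = qc_rep, selection_report = sel_rep,
                        norm_constants = nconst, config = config,
                        counts = counts),
                   class = "theta_run")
  run$manifest <- build_manifest(run, outdir)
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

run_tables <- function(run) {
  list(
    image_profiles = run$images,
    well_profiles = run$wells,
    normalized_profiles = run$normalized,
    pc_coordinates = run$centered,
    activity = run$activity,
    zprime = run$zprime,
    theta = run$theta,
    delta_theta = run$deltas,
    ranked_pairs = run$ranked,
    hit_list = run$hits,
    qc_report = run$qc_report,
    feature_selection = dplyr::bind_rows(
      dplyr::mutate(run$selection_report$removed_by_variance,
                    rule = "variance", .before = 1),
      tibble::tibble(rule = "correlation",
                     feature = run$selection_report$removed_by_correlation$removed)
    ),
    norm_constants = run$norm_constants,
    pc_model = tibble::as_tibble(run$pca$rotation[, seq_len(run$pca$k),
                                                  drop = FALSE]) |>
      dplyr::mutate(feature = run$pca$features, .before = 1)
  )
}

build_manifest <- function(run, outdir) {
  list(
    tool = "thetascreen",
    version = as.character(utils::packageVersion("thetascreen")),
    config = unclass(run$config),
    config_hash = config_hash(run$config),
    seed = run$config$seed,
    counts = run$counts,
    zprime = setNames(as.list(run$zprime$zprime), run$zprime$cell_line),
    outputs = list()  # filled on write
  )
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- run_tables(run)
  hashes <- list()
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]]) || nrow(tabs[[nm]]) == 0) next
    path <- file.path(outdir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], path)
    hashes[[paste0(nm, ".csv")]] <- unname(tools::md5sum(path))
  }
  run$manifest$outputs <- hashes
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(run$manifest)
}

#' @export
print.theta_run <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("<theta_run> %d wells on %d plates; %d features retained; k = %d PCs\n",
              c0$wells, length(unique(x$wells$plate)), c0$features_retained,
              c0$pc_retained))
  cat(sprintf("  %d active compound calls; %d ranked pairs; %d hits\n",
              c0$n_active_calls, c0$n_ranked_pairs, c0$n_hits))
  zp <- x$zprime
  cat(sprintf("  Z' pooled %.2f (per-line %s)\n",
              zp$zprime[zp$cell_line == "pooled"],
              paste(sprintf("%.2f", zp$zprime[zp$cell_line != "pooled"]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
glance.theta_run <- function(x, ...) {
  tibble::tibble(
    n_wells = x$counts$wells,
    n_features = x$counts$features_retained,
    k = x$counts$pc_retained,
    n_active_calls = x$counts$n_active_calls,
    n_ranked_pairs = x$counts$n_ranked_pairs,
    n_hits = x$counts$n_hits,
    zprime_pooled = x$zprime$zprime[x$zprime$cell_line == "pooled"]
  )
}

#' @export
tidy.theta_run <- function(x, ...) x$hits
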
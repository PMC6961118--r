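# Built-in CSV dialects: how identifier and QC columns are named in the
# source file. Everything not mapped is a candidate feature column.
DIALECTS <- list(
  generic = c(plate = "plate", well = "well", image = "image_id",
              object = "object_id", saturation = "qc_saturation",
              focus = "qc_focus"),
  cellprofiler = c(plate = "Metadata_Plate", well = "Metadata_Well",
                   image = "ImageNumber", object = "ObjectNumber",
                   saturation = "ImageQuality_PercentMaximal",
                   focus = "ImageQuality_FocusScore")
)

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1) {
    if (!dialect %in% names(DIALECTS))
      abort(sprintf("unknown dialect '%s' (built-in: %s)", dialect,
                    paste(names(DIALECTS), collapse = ", ")),
            class = "thetascreen_config_error")
    return(DIALECTS[[dialect]])
  }
  dialect <- unlist(dialect)
  if (!all(c("plate", "well", "image", "object") %in% names(dialect)))
    abort("a custom dialect must map at least plate, well, image and object",
          class = "thetascreen_config_error")
  dialect
}

#' Read a per-cell feature table
#'
#' Reads a CellProfiler-style CSV export (one row per segmented object) and
#' maps its identifier and image-QC columns to the package's canonical names
#' (`plate`, `well`, `image_id`, `object_id`, `qc_saturation`, `qc_focus`).
#' All remaining columns are treated as morphological features and coerced to
#' numeric; cells that do not parse become missing values. Rows with a
#' missing identifier are rejected and their count reported.
#'
#' @param path CSV file with a header row.
#' @param dialect `"generic"` (canonical names), `"cellprofiler"`
#'   (`Metadata_Plate`, `Metadata_Well`, `ImageNumber`, `ObjectNumber`, ...),
#'   or a named character vector mapping `plate`/`well`/`image`/`object` (and
#'   optionally `saturation`/`focus`) to source column names.
#' @return Tibble keyed by (`plate`, `well`, `image_id`, `object_id`) with
#'   numeric feature columns; the number of rejected rows is attached as
#'   attribute `"n_rejected"`.
#' @export
read_feature_table <- function(path, dialect = "generic") {
  map <- resolve_dialect(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) == 0)
    abort(sprintf("empty feature table: %s", path),
          class = "thetascreen_format_error")
  for (key in c("plate", "well", "image", "object")) {
    if (!map[[key]] %in% names(raw))
      abort(sprintf("feature table lacks identifier column '%s' (%s)",
                    map[[key]], key),
            class = "thetascreen_format_error")
  }
  canon <- c(plate = "plate", well = "well", image = "image_id",
             object = "object_id", saturation = "qc_saturation",
             focus = "qc_focus")
  present <- names(map)[map %in% names(raw)]
  out <- raw
  names(out)[match(map[present], names(out))] <- canon[present]
  feat <- setdiff(names(out), canon)
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(
    intersect(c("qc_saturation", "qc_focus", feat), names(out))),
    ~ suppressWarnings(as.numeric(.x))))
  keys <- c("plate", "well", "image_id", "object_id")
  bad <- !stats::complete.cases(out[keys])
  if (any(bad)) {
    inform(sprintf("rejected %d row(s) with missing identifiers", sum(bad)))
    out <- out[!bad, ]
  }
  structure(tibble::as_tibble(out), n_rejected = sum(bad))
}

#' Read a plate map
#'
#' @param path CSV with columns `plate`, `well`, `compound`, `conc`, `role`,
#'   `cell_line`, `replicate`; `role` must be one of `treatment`, `negctrl`,
#'   `posctrl`.
#' @return Tibble plate map, validated by [validate_layout()] rules on roles.
#' @export
read_plate_layout <- function(path) {
  lay <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(lay, c("plate", "well", "compound", "conc", "role",
                     "cell_line", "replicate"), "plate map")
  bad_role <- setdiff(unique(lay$role), ROLES)
  if (length(bad_role) > 0)
    abort(sprintf("plate map has unknown role(s): %s",
                  paste(bad_role, collapse = ", ")),
          class = "thetascreen_format_error")
  tibble::as_tibble(lay)
}

#' Check a plate map against a profile table
#'
#' Asserts that every (`plate`, `well`) in the table appears exactly once in
#' the layout and that every plate carries at least two negative- and two
#' positive-control wells.
#'
#' @param table A cell/image/well-level table with `plate` and `well`.
#' @param layout A plate map.
#' @return Invisibly `layout`.
#' @export
validate_layout <- function(table, layout) {
  assert_cols(layout, c("plate", "well", "role"), "plate map")
  key <- paste(layout$plate, layout$well)
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    abort(sprintf("plate map lists well(s) more than once: %s",
                  paste(head(dup, 3), collapse = ", ")),
          class = "thetascreen_layout_error")
  missing <- setdiff(unique(paste(table$plate, table$well)), key)
  if (length(missing) > 0)
    abort(sprintf("%d well(s) in the data are absent from the plate map (e.g. %s)",
                  length(missing), paste(head(missing, 3), collapse = ", ")),
          class = "thetascreen_layout_error")
  ctrl <- dplyr::count(dplyr::filter(layout, .data$role != "treatment"),
                       .data$plate, .data$role)
  counts <- tidyr::complete(ctrl, plate = unique(layout$plate),
                            role = c("negctrl", "posctrl"),
                            fill = list(n = 0L))
  short <- dplyr::filter(counts, .data$n < 2)
  if (nrow(short) > 0)
    abort(sprintf("plate %s has < 2 %s wells", short$plate[1], short$role[1]),
          class = "thetascreen_layout_error")
  invisible(layout)
}

#' Annotate profiles with the plate map
#'
#' Left-joins plate-map columns onto a profile table by (`plate`, `well`) and
#' fails loudly if any profile row is left unannotated.
#'
#' @param table A profile table with `plate` and `well` columns.
#' @param layout A plate map.
#' @return The annotated tibble.
#' @export
join_layout <- function(table, layout) {
  out <- dplyr::left_join(table,
                          dplyr::select(layout, dplyr::all_of(
                            c("plate", "well", "compound", "conc", "role",
                              "cell_line", "replicate"))),
                          by = c("plate", "well"))
  if (anyNA(out$role))
    abort(sprintf("%d profile row(s) have no plate-map entry",
                  sum(is.na(out$role))),
          class = "thetascreen_layout_error")
  out
}

#' Remove objects from images that fail quality control
#'
#' Drops every object belonging to an image whose saturation fraction
#' exceeds `sat_max` or whose focus score falls below the focus cutoff.
#' When `focus_min` is `NULL` it is self-calibrated per plate as the 1st
#' percentile of the focus scores of that plate's negative-control images
#' (of all images if no `layout` is given), so no absolute focus scale is
#' assumed.
#'
#' @param cells Cell-level table with `qc_saturation` and `qc_focus`.
#' @param layout Optional plate map (used only to locate negative-control
#'   images for focus self-calibration).
#' @param sat_max Maximum tolerated saturation fraction (default 0.2).
#' @param focus_min Absolute focus cutoff, or `NULL` for self-calibration.
#' @return The filtered tibble, with a `"qc_report"` attribute (tibble of
#'   removed `image_id`, `plate`, `well`, `reason`) retrievable with
#'   [qc_report()].
#' @export
qc_filter_images <- function(cells, layout = NULL, sat_max = 0.2,
                             focus_min = NULL) {
  missing_qc <- setdiff(c("qc_saturation", "qc_focus"), names(cells))
  if (length(missing_qc) > 0)
    abort(sprintf("QC is enabled but column(s) %s are absent; disable QC or supply them",
                  paste(missing_qc, collapse = ", ")),
          class = "thetascreen_config_error")
  imgs <- dplyr::distinct(cells, .data$plate, .data$well, .data$image_id,
                          .data$qc_saturation, .data$qc_focus)
  if (is.null(focus_min)) {
    ref <- imgs
    if (!is.null(layout)) {
      neg <- dplyr::filter(layout, .data$role == "negctrl")
      ref <- dplyr::semi_join(imgs, neg, by = c("plate", "well"))
    }
    # half the negctrl 1st percentile: with a handful of control images the
    # raw percentile sits at the sample minimum and would spuriously reject
    # ~1/(n+1) of healthy images; halving keeps the cutoff scale-free while
    # leaving a guard band below the in-focus distribution
    cuts <- dplyr::summarise(dplyr::group_by(ref, .data$plate),
                             focus_cut = 0.5 * quantile(.data$qc_focus, 0.01,
                                                        na.rm = TRUE,
                                                        names = FALSE),
                             .groups = "drop")
  } else {
    cuts <- tibble::tibble(plate = unique(imgs$plate), focus_cut = focus_min)
  }
  imgs <- dplyr::left_join(imgs, cuts, by = "plate")
  imgs$fail_sat <- !is.na(imgs$qc_saturation) & imgs$qc_saturation > sat_max
  imgs$fail_foc <- !is.na(imgs$qc_focus) & !is.na(imgs$focus_cut) &
    imgs$qc_focus < imgs$focus_cut
  removed <- dplyr::filter(imgs, .data$fail_sat | .data$fail_foc)
  report <- dplyr::transmute(
    removed,
    image_id = .data$image_id, plate = .data$plate, well = .data$well,
    reason = dplyr::case_when(
      .data$fail_sat & .data$fail_foc ~ "saturation+focus",
      .data$fail_sat ~ "saturation",
      TRUE ~ "focus"
    ))
  out <- dplyr::filter(cells, !.data$image_id %in% report$image_id)
  structure(out, qc_report = report)
}

#' @rdname qc_filter_images
#' @param x Result of [qc_filter_images()].
#' @export
qc_report <- function(x) attr(x, "qc_report")

agg_median <- function(df, by, n_col) {
  feats <- feature_cols(df)
  dt <- data.table::as.data.table(df)
  # two grouped queries so data.table's optimised grouped median kicks in
  meds <- dt[, lapply(.SD, median, na.rm = TRUE), keyby = by, .SDcols = feats]
  ns <- dt[, .N, keyby = by]
  data.table::setnames(ns, "N", n_col)
  agg <- ns[meds]
  out <- tibble::as_tibble(agg)
  n_missing <- sum(vapply(out[feats], function(v) sum(is.na(v)), integer(1)))
  if (n_missing > 0)
    warn(sprintf("%d aggregated feature value(s) are missing (all contributing values missing)",
                 n_missing))
  out
}

#' Aggregate single cells to per-image medians
#'
#' One row per image; each feature is the median over that image's objects,
#' ignoring missing values, with the contributing object count in
#' `n_objects`.
#'
#' @param cells Cell-level feature table.
#' @return Image-level profile tibble.
#' @export
aggregate_to_image_median <- function(cells) {
  assert_cols(cells, c("plate", "well", "image_id"), "cell table")
  agg_median(cells, by = c("plate", "well", "image_id"), n_col = "n_objects")
}

#' Aggregate image profiles to per-well medians
#'
#' One row per well; each feature is the median of the image medians, with
#' the contributing image count in `n_images`. The well profile is the unit
#' of all downstream per-compound scoring.
#'
#' @param images Image-level profile table from [aggregate_to_image_median()].
#' @return Well-level profile tibble.
#' @export
aggregate_to_well <- function(images) {
  assert_cols(images, c("plate", "well"), "image profile table")
  agg_median(images, by = c("plate", "well"), n_col = "n_images")
}
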
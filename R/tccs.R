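#' Theta comparative cell scoring: per-compound phenotype angle
#'
#' For each compound x cell line x replicate, the compound-level coordinates
#' (component-wise median of its wells within the replicate) are reduced to
#' the 2-D angle `theta = atan2(PC2, PC1)` measured counter-clockwise from
#' the positive PC1 axis, in degrees in \[0, 360), together with the l2
#' magnitude in the PC1-PC2 plane. A direction is only meaningful for a
#' compound that actually moved the phenotype: theta is flagged undefined
#' when the magnitude is zero, when it falls below `magnitude_floor`, or —
#' if an activity table is supplied — when the compound is inactive in that
#' cell line (the recommended rule: direction validity follows the activity
#' call).
#'
#' @param centered Centered PC table from [project_and_center()] with at
#'   least 2 retained components and `compound`, `cell_line`, `role` (and
#'   optionally `replicate`) columns.
#' @param activity Optional [call_activity()] table used as the definedness
#'   rule.
#' @param magnitude_floor Optional absolute magnitude below which theta is
#'   undefined.
#' @return Tibble of `compound`, `cell_line`, `replicate`, `theta_deg`,
#'   `magnitude`, `theta_defined`.
#' @export
compute_theta <- function(centered, activity = NULL, magnitude_floor = NULL) {
  pcs <- pc_cols(centered)
  if (length(pcs) < 2)
    abort("theta needs at least 2 retained principal components",
          class = "thetascreen_pipeline_error")
  coords <- compound_coords(centered, by_replicate = TRUE)
  out <- coords |>
    dplyr::mutate(
      magnitude = sqrt(.data$PC1^2 + .data$PC2^2),
      theta_deg = (atan2(.data$PC2, .data$PC1) * 180 / pi) %% 360,
      theta_defined = .data$magnitude > 0
    )
  if (!is.null(magnitude_floor))
    out$theta_defined <- out$theta_defined & out$magnitude >= magnitude_floor
  if (!is.null(activity)) {
    act <- dplyr::select(activity, dplyr::all_of(c("compound", "cell_line",
                                                   "active")))
    out <- dplyr::left_join(out, act, by = c("compound", "cell_line"))
    out$theta_defined <- out$theta_defined & !is.na(out$active) & out$active
    out$active <- NULL
  }
  out$theta_deg[!out$theta_defined] <- NA_real_
  dplyr::select(out, dplyr::all_of(c("compound", "cell_line", "replicate",
                                     "theta_deg", "magnitude",
                                     "theta_defined")))
}

#' Angular divergence between cell-line pairs
#'
#' For every compound and replicate, pairs the theta records of all cell
#' lines and computes the wrap-around angular difference
#' `delta = min(|a - b|, 360 - |a - b|)`, in \[0, 180\]. Pairs are unordered
#' and reported with `line_a < line_b`. Pairs with an undefined theta on
#' either side carry a missing delta (they are excluded from ranking and
#' counted in the `"n_undefined"` attribute).
#'
#' @param theta Theta table from [compute_theta()].
#' @return Tibble of `compound`, `line_a`, `line_b`, `replicate`,
#'   `delta_theta_deg`.
#' @export
delta_theta <- function(theta) {
  assert_cols(theta, c("compound", "cell_line", "replicate", "theta_deg"),
              "theta table")
  pairs <- dplyr::inner_join(theta, theta, by = c("compound", "replicate"),
                             suffix = c("_a", "_b"),
                             relationship = "many-to-many") |>
    dplyr::filter(.data$cell_line_a < .data$cell_line_b) |>
    dplyr::transmute(
      compound = .data$compound,
      line_a = .data$cell_line_a,
      line_b = .data$cell_line_b,
      replicate = .data$replicate,
      delta_theta_deg = angle_diff(.data$theta_deg_a, .data$theta_deg_b)
    )
  structure(pairs, n_undefined = sum(is.na(pairs$delta_theta_deg)))
}

#' Full-dimensional angular divergence (k-D variant)
#'
#' Alternative to the 2-D [delta_theta()]: the angle between the two cell
#' lines' full k-dimensional compound coordinate vectors,
#' `arccos(v_a . v_b / (|v_a| |v_b|))`, in degrees in \[0, 180\]. Reported
#' separately; the 2-D plane angle is the default method.
#'
#' @param centered Centered PC table from [project_and_center()].
#' @param activity Optional activity table; pairs with an inactive member
#'   get a missing angle.
#' @return Tibble as [delta_theta()].
#' @export
delta_theta_kd <- function(centered, activity = NULL) {
  coords <- compound_coords(centered, by_replicate = TRUE)
  pcs <- pc_cols(coords)
  if (!is.null(activity)) {
    act <- dplyr::select(activity, dplyr::all_of(c("compound", "cell_line",
                                                   "active")))
    coords <- dplyr::left_join(coords, act, by = c("compound", "cell_line"))
  } else {
    coords$active <- TRUE
  }
  pairs <- dplyr::inner_join(coords, coords, by = c("compound", "replicate"),
                             suffix = c("_a", "_b"),
                             relationship = "many-to-many") |>
    dplyr::filter(.data$cell_line_a < .data$cell_line_b)
  va <- as.matrix(pairs[paste0(pcs, "_a")])
  vb <- as.matrix(pairs[paste0(pcs, "_b")])
  na <- sqrt(rowSums(va^2))
  nb <- sqrt(rowSums(vb^2))
  cosv <- rowSums(va * vb) / (na * nb)
  ang <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  ang[na == 0 | nb == 0 | !pairs$active_a | !pairs$active_b] <- NA_real_
  out <- dplyr::transmute(pairs,
                          compound = .data$compound,
                          line_a = .data$cell_line_a,
                          line_b = .data$cell_line_b,
                          replicate = .data$replicate)
  out$delta_theta_deg <- ang
  structure(out, n_undefined = sum(is.na(ang)))
}

#' Rank-product ordering of compound/cell-line pairs across replicates
#'
#' Within each replicate, compound/cell-line-pair items are ranked by
#' decreasing divergence (rank 1 = largest delta-theta; ties get fractional
#' average ranks). The rank product of an item is the geometric mean of its
#' per-replicate ranks, and the hit list is sorted by increasing rank
#' product, so consistently divergent pairs come first. Items with a missing
#' delta in any replicate are excluded and reported. Equal rank products are
#' broken by larger mean delta-theta, then lexicographically.
#'
#' @param deltas Delta-theta table from [delta_theta()].
#' @return Tibble of `final_rank`, `compound`, `line_a`, `line_b`,
#'   `mean_delta_theta`, `rank_product`, with the per-replicate rank audit
#'   table attached as attribute `"replicate_ranks"` (see
#'   [replicate_ranks()]).
#' @export
rank_product <- function(deltas) {
  assert_cols(deltas, c("compound", "line_a", "line_b", "replicate",
                        "delta_theta_deg"), "delta-theta table")
  ok <- !is.na(deltas$delta_theta_deg)
  if (!all(ok))
    inform(sprintf("%d record(s) with undefined delta-theta excluded from ranking",
                   sum(!ok)))
  d <- deltas[ok, ]
  if (nrow(d) == 0)
    abort("no defined delta-theta records to rank",
          class = "thetascreen_pipeline_error")
  n_reps <- length(unique(d$replicate))
  d <- d |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(rep_rank = rank(-.data$delta_theta_deg,
                                  ties.method = "average")) |>
    dplyr::ungroup()
  per_item <- d |>
    dplyr::group_by(.data$compound, .data$line_a, .data$line_b) |>
    dplyr::summarise(
      n_reps_present = dplyr::n(),
      mean_delta_theta = mean(.data$delta_theta_deg),
      rank_product = exp(mean(log(.data$rep_rank))),
      .groups = "drop"
    )
  dropped <- dplyr::filter(per_item, .data$n_reps_present < n_reps)
  if (nrow(dropped) > 0) {
    warn(sprintf("%d item(s) missing from some replicate were excluded from the ranking",
                 nrow(dropped)))
    per_item <- dplyr::filter(per_item, .data$n_reps_present == n_reps)
    # re-rank within replicates over the complete items only
    d <- dplyr::semi_join(d, per_item, by = c("compound", "line_a", "line_b")) |>
      dplyr::group_by(.data$replicate) |>
      dplyr::mutate(rep_rank = rank(-.data$delta_theta_deg,
                                    ties.method = "average")) |>
      dplyr::ungroup()
    per_item <- d |>
      dplyr::group_by(.data$compound, .data$line_a, .data$line_b) |>
      dplyr::summarise(
        n_reps_present = dplyr::n(),
        mean_delta_theta = mean(.data$delta_theta_deg),
        rank_product = exp(mean(log(.data$rep_rank))),
        .groups = "drop"
      )
  }
  out <- per_item |>
    dplyr::arrange(.data$rank_product, dplyr::desc(.data$mean_delta_theta),
                   .data$compound, .data$line_a, .data$line_b) |>
    dplyr::mutate(final_rank = dplyr::row_number()) |>
    dplyr::select(dplyr::all_of(c("final_rank", "compound", "line_a",
                                  "line_b", "mean_delta_theta",
                                  "rank_product")))
  structure(out, replicate_ranks = dplyr::select(
    d, dplyr::all_of(c("compound", "line_a", "line_b", "replicate",
                       "delta_theta_deg", "rep_rank"))))
}

#' @rdname rank_product
#' @param x Result of [rank_product()].
#' @export
replicate_ranks <- function(x) attr(x, "replicate_ranks")

#' Assemble the final hit list
#'
#' Restricts the rank-product ordering to compounds active in every cell
#' line, honours an optional manual exclusion list (mechanism-of-action
#' triage is not automated), renumbers the ranks, and truncates to the top
#' `top_n` pairs.
#'
#' @param ranked [rank_product()] output.
#' @param activity Optional [call_activity()] table spanning all cell lines;
#'   when given, only pan-active compounds (see [filter_pan_active()]) are
#'   kept.
#' @param top_n Number of pairs to keep (default all).
#' @param exclude Character vector (or path to a plain-text file, one id per
#'   line) of compound ids to drop; unknown ids produce a warning and are
#'   ignored.
#' @return Tibble of `final_rank`, `compound`, `line_a`, `line_b`,
#'   `mean_delta_theta`, `rank_product`.
#' @export
build_hit_list <- function(ranked, activity = NULL, top_n = Inf,
                           exclude = NULL) {
  out <- ranked
  if (!is.null(activity)) {
    pan <- filter_pan_active(activity)
    out <- dplyr::filter(out, .data$compound %in% pan)
  }
  if (!is.null(exclude)) {
    if (length(exclude) == 1 && file.exists(exclude))
      exclude <- readLines(exclude, warn = FALSE)
    exclude <- trimws(exclude)
    exclude <- exclude[nzchar(exclude)]
    unknown <- setdiff(exclude, ranked$compound)
    if (length(unknown) > 0)
      warn(sprintf("exclusion list names %d unknown compound(s): %s",
                   length(unknown), paste(head(unknown, 3), collapse = ", ")))
    out <- dplyr::filter(out, !.data$compound %in% exclude)
  }
  out |>
    dplyr::arrange(.data$final_rank) |>
    dplyr::mutate(final_rank = dplyr::row_number()) |>
    head(n = if (is.finite(top_n)) top_n else nrow(out))
}
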
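# number of components whose cumulative variance fraction first reaches p,
# never counting components beyond the numerical rank; floored at 2 (the
# angular scoring downstream is two-dimensional) whenever the rank allows
choose_k <- function(var_frac, variance_prop) {
  rank <- sum(var_frac > max(var_frac) * 1e-12)
  k <- which(cumsum(var_frac) >= variance_prop - 1e-12)[1]
  if (is.na(k)) k <- length(var_frac)
  as.integer(min(max(k, 2L), rank))
}

#' Fit the shared principal-component phenotype space
#'
#' PCA on the normalized profile matrix with no further centering or scaling
#' (the data are already standardized to the plate DMSO null). The number of
#' retained components `k` is the smallest number whose cumulative variance
#' fraction reaches `variance_prop`, floored at two whenever the matrix rank
#' allows (the downstream angular scoring lives in the PC1-PC2 plane).
#' Loadings carry a deterministic sign convention: the largest-magnitude
#' element of each loading vector is made positive.
#'
#' @param normalized Normalized profile table from [normalize_to_dmso()].
#' @param variance_prop Proportion of variance to retain, in (0, 1];
#'   default 0.5 (the leading components that carry compound-displacement
#'   signal, excluding the isotropic per-feature noise floor).
#' @return A `pheno_pca` object (loadings, component standard deviations,
#'   variance fractions, retained `k`). Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_pca <- function(normalized, variance_prop = 0.5) {
  if (!is.numeric(variance_prop) || variance_prop <= 0 || variance_prop > 1)
    abort("variance_prop must be in (0, 1]", class = "thetascreen_config_error")
  feats <- feature_cols(normalized)
  if (length(feats) < 2 || nrow(normalized) < 2)
    abort("PCA needs at least 2 wells and 2 features",
          class = "thetascreen_pipeline_error")
  x <- as.matrix(normalized[feats])
  pr <- prcomp(x, center = FALSE, scale. = FALSE)
  rot <- pr$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip]
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  k <- choose_k(var_frac, variance_prop)
  structure(list(rotation = rot, sdev = pr$sdev, var_frac = var_frac,
                 k = k, variance_prop = variance_prop, features = feats,
                 n_rows = nrow(x)),
            class = "pheno_pca")
}

#' @export
print.pheno_pca <- function(x, ...) {
  cat(sprintf("<pheno_pca> %d features, %d wells; k = %d components retain >= %.0f%% variance\n",
              length(x$features), x$n_rows, x$k, 100 * x$variance_prop))
  invisible(x)
}

#' @export
tidy.pheno_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$sdev),
    sdev = x$sdev,
    var_frac = x$var_frac,
    cumulative = cumsum(x$var_frac),
    retained = seq_along(x$sdev) <= x$k
  )
}

#' @export
glance.pheno_pca <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), n_wells = x$n_rows,
                 k = x$k, variance_prop = x$variance_prop,
                 var_explained = sum(x$var_frac[seq_len(x$k)]))
}

#' Project profiles and center on the negative control
#'
#' Projects every well onto the retained principal components and subtracts
#' the per-component median of the negative-control wells, so the negative
#' control centroid sits exactly at the origin of the phenotype space.
#'
#' @param pca A [fit_pca()] model.
#' @param normalized Normalized profile table with the model's feature
#'   columns and a `role` column (or supply `layout`).
#' @param layout Optional plate map for annotation.
#' @return Tibble of metadata plus `PC1..PCk` coordinates; the subtracted
#'   offset vector is attached as attribute `"offset"`.
#' @export
project_and_center <- function(pca, normalized, layout = NULL) {
  stopifnot(inherits(pca, "pheno_pca"))
  if (!"role" %in% names(normalized)) {
    if (is.null(layout))
      abort("project_and_center needs a 'role' column or a plate map",
            class = "thetascreen_config_error")
    normalized <- join_layout(normalized, layout)
  }
  missing <- setdiff(pca$features, names(normalized))
  if (length(missing) > 0)
    abort(sprintf("profiles lack %d feature(s) used by the PC model (e.g. %s)",
                  length(missing), paste(head(missing, 3), collapse = ", ")),
          class = "thetascreen_format_error")
  scores <- as.matrix(normalized[pca$features]) %*%
    pca$rotation[, seq_len(pca$k), drop = FALSE]
  neg <- normalized$role == "negctrl"
  if (!any(neg))
    abort("no negative-control rows to center on",
          class = "thetascreen_pipeline_error")
  offset <- apply(scores[neg, , drop = FALSE], 2, median)
  scores <- sweep(scores, 2, offset, "-")
  colnames(scores) <- paste0("PC", seq_len(pca$k))
  out <- dplyr::bind_cols(
    normalized[setdiff(names(normalized), pca$features)],
    tibble::as_tibble(scores))
  structure(out, offset = offset)
}

# per compound x cell line (x replicate if requested) coordinates:
# component-wise median over the compound's wells
compound_coords <- function(centered, by_replicate = FALSE) {
  assert_cols(centered, c("compound", "cell_line", "role"), "centered table")
  pcs <- pc_cols(centered)
  by <- c("compound", "cell_line", if (by_replicate) "replicate")
  if (by_replicate && !"replicate" %in% names(centered))
    centered$replicate <- 1L
  centered |>
    dplyr::filter(.data$role == "treatment") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pcs), median),
                     n_wells = dplyr::n(), .groups = "drop")
}

#' Call compound activity from l1 distance to the control centroid
#'
#' For each cell line, compound-level coordinates (the component-wise median
#' of the compound's wells) are reduced to the l1 norm — the sum of absolute
#' PC coordinates, i.e. the city-block distance to the negative-control
#' centroid at the origin. The activity cutoff is `k_sd` times the standard
#' deviation (n-1 denominator) of all compound distances in that cell line;
#' a compound is active when its distance exceeds the cutoff.
#'
#' @param centered Centered PC table from [project_and_center()] with
#'   `compound`, `cell_line` and `role` columns.
#' @param k_sd Multiplier on the distance SD (default 2).
#' @return Tibble of `compound`, `cell_line`, `l1_distance`, `threshold`,
#'   `active`, `n_wells`.
#' @export
call_activity <- function(centered, k_sd = 2) {
  coords <- compound_coords(centered, by_replicate = FALSE)
  pcs <- pc_cols(coords)
  coords$l1_distance <- rowSums(abs(as.matrix(coords[pcs])))
  out <- coords |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3)
        abort(sprintf("cell line %s has < 3 compounds; distance SD is unstable",
                      key$cell_line),
              class = "thetascreen_pipeline_error")
      df$threshold <- k_sd * sd(df$l1_distance)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(active = .data$l1_distance > .data$threshold) |>
    dplyr::select(dplyr::all_of(c("compound", "cell_line", "l1_distance",
                                  "threshold", "active", "n_wells")))
  out
}

#' Compounds active in every cell line
#'
#' A compound inactive in any one screened cell line is removed from the
#' divergence analysis; the survivors are the pan-active set. Compounds not
#' scored in every cell line are excluded with a warning.
#'
#' @param activity Activity table from [call_activity()] covering all cell
#'   lines.
#' @return Character vector of pan-active compound ids, with a per-cell-line
#'   active-count tibble attached as attribute `"active_counts"`
#'   (retrievable with [active_counts()]).
#' @export
filter_pan_active <- function(activity) {
  assert_cols(activity, c("compound", "cell_line", "active"), "activity table")
  n_lines <- length(unique(activity$cell_line))
  per_compound <- activity |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(n_lines_scored = dplyr::n(),
                     n_active = sum(.data$active), .groups = "drop")
  incomplete <- per_compound$compound[per_compound$n_lines_scored < n_lines]
  if (length(incomplete) > 0)
    warn(sprintf("%d compound(s) not scored in every cell line were excluded",
                 length(incomplete)))
  pan <- per_compound$compound[per_compound$n_lines_scored == n_lines &
                                 per_compound$n_active == n_lines]
  counts <- activity |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(n_active = sum(.data$active), .groups = "drop")
  structure(sort(pan), active_counts = counts)
}

#' @rdname filter_pan_active
#' @param x Result of [filter_pan_active()].
#' @export
active_counts <- function(x) attr(x, "active_counts")

#' Z'-factor from control projections
#'
#' The screening-window statistic
#' `Z' = 1 - 3 (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|` on
#' one-dimensional control readouts. Always at most 1; 0 marks the
#' conventional boundary of a usable assay.
#'
#' @param neg,pos Numeric vectors of negative/positive-control readouts
#'   (at least 2 each).
#' @return The Z' value; `-Inf` (with a warning) when the control means
#'   coincide.
#' @examples
#' zprime(rnorm(64, 0, 1), rnorm(64, 10, 1)) # about 0.4
#' @export
zprime <- function(neg, pos) {
  if (length(neg) < 2 || length(pos) < 2)
    abort("zprime needs >= 2 readouts per control class",
          class = "thetascreen_pipeline_error")
  denom <- abs(mean(pos) - mean(neg))
  if (denom == 0) {
    warn("control means coincide; Z' undefined (reported as -Inf)")
    return(-Inf)
  }
  1 - 3 * (sd(pos) + sd(neg)) / denom
}

#' Multivariate Z'-factor between plate controls
#'
#' Generalizes the Z'-factor to multi-feature control profiles by projecting
#' every control well onto the axis joining the negative- and
#' positive-control component-wise medians, then applying the univariate
#' formula to the projections. Scores are computed per cell line and pooled
#' over the concatenated (per-plate normalized, hence per-line comparable)
#' controls.
#'
#' @param profiles Normalized profile table (feature space, the default) or
#'   a centered PC table; must carry `role` and `cell_line` columns (or
#'   supply `layout`).
#' @param layout Optional plate map for annotation.
#' @return Tibble of `cell_line` (including `"pooled"`), `zprime`,
#'   `separation` (distance between projected control means), `n_neg`,
#'   `n_pos`.
#' @export
multivariate_zprime <- function(profiles, layout = NULL) {
  if (!all(c("role", "cell_line") %in% names(profiles))) {
    if (is.null(layout))
      abort("multivariate_zprime needs 'role'/'cell_line' columns or a plate map",
            class = "thetascreen_config_error")
    profiles <- join_layout(profiles, layout)
  }
  cols <- pc_cols(profiles)
  if (length(cols) == 0) cols <- feature_cols(profiles)
  score_one <- function(df, label) {
    xn <- as.matrix(df[df$role == "negctrl", cols, drop = FALSE])
    xp <- as.matrix(df[df$role == "posctrl", cols, drop = FALSE])
    if (nrow(xn) < 2 || nrow(xp) < 2)
      abort(sprintf("%s: need >= 2 wells per control class", label),
            class = "thetascreen_pipeline_error")
    axis <- apply(xp, 2, median) - apply(xn, 2, median)
    len <- sqrt(sum(axis^2))
    if (len == 0) {
      warn(sprintf("%s: control medians coincide; Z' undefined", label))
      return(tibble::tibble(cell_line = label, zprime = -Inf, separation = 0,
                            n_neg = nrow(xn), n_pos = nrow(xp)))
    }
    u <- axis / len
    pn <- as.vector(xn %*% u)
    pp <- as.vector(xp %*% u)
    tibble::tibble(cell_line = label, zprime = zprime(pn, pp),
                   separation = abs(mean(pp) - mean(pn)),
                   n_neg = nrow(xn), n_pos = nrow(xp))
  }
  ctrl <- dplyr::filter(profiles, .data$role %in% c("negctrl", "posctrl"))
  per_line <- ctrl |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::group_map(~ score_one(.x, .y$cell_line)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_line, score_one(ctrl, "pooled"))
}
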
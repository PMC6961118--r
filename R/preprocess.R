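#' Remove uninformative and redundant features
#'
#' Two-stage feature selection on well profiles, applied globally so that
#' every cell line keeps the same feature basis. First, features with
#' variance below `var_threshold` (or zero) are dropped; when `layout` is
#' supplied the variance is computed per cell line over that line's pooled
#' plates, and a feature is dropped if it is uninformative in any line.
#' Second, greedy correlation pruning: while any retained pair has
#' `|Pearson r| > corr_threshold`, the most correlated offending pair is
#' found and the member with the larger mean `|r|` against all other
#' retained features is removed (ties broken alphabetically, keeping the
#' earlier name). The procedure is deterministic given the (alphabetical)
#' column order and idempotent.
#'
#' @param wells Well-level profile table.
#' @param layout Optional plate map (gives the per-cell-line variance
#'   grouping).
#' @param corr_threshold Absolute Pearson correlation above which a pair is
#'   redundant (default 0.9).
#' @param var_threshold Variance below which a feature is uninformative
#'   (default 1e-5).
#' @return The table restricted to retained features, with a
#'   `"selection_report"` attribute (see [selection_report()]).
#' @export
select_features <- function(wells, layout = NULL, corr_threshold = 0.9,
                            var_threshold = 1e-5) {
  feats <- sort(feature_cols(wells))
  if (length(feats) < 2)
    abort("need at least 2 feature columns", class = "thetascreen_pipeline_error")
  if (nrow(wells) < 2)
    abort("need at least 2 wells for feature selection",
          class = "thetascreen_pipeline_error")
  x <- as.matrix(wells[feats])

  if (!is.null(layout) && !"cell_line" %in% names(wells)) {
    wells_ann <- join_layout(wells, layout)
  } else {
    wells_ann <- wells
  }
  if ("cell_line" %in% names(wells_ann)) {
    grp <- split(seq_len(nrow(x)), wells_ann$cell_line)
    vars <- vapply(feats, function(f) {
      min(vapply(grp, function(ix) var(x[ix, f], na.rm = TRUE), numeric(1)))
    }, numeric(1))
  } else {
    vars <- apply(x, 2, var, na.rm = TRUE)
  }
  low_var <- is.na(vars) | vars < var_threshold
  removed_var <- tibble::tibble(feature = feats[low_var],
                                variance = unname(vars[low_var]))
  keep <- feats[!low_var]
  if (length(keep) < 2)
    abort("fewer than 2 features retained after the variance filter",
          class = "thetascreen_pipeline_error")

  cmat <- abs(cor(x[, keep, drop = FALSE], use = "pairwise.complete.obs"))
  cmat[is.na(cmat)] <- 0
  diag(cmat) <- 0
  removed_corr <- list()
  while (length(keep) >= 2 && max(cmat) > corr_threshold) {
    mx <- max(cmat)
    hit <- which(cmat == mx, arr.ind = TRUE)
    # deterministic pair choice: lexicographically first (row < col) pair
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    pair <- rownames(cmat)[hit[order(hit[, 1], hit[, 2])[1], ]]
    mean_r <- rowSums(cmat[pair, , drop = FALSE]) / (ncol(cmat) - 1)
    drop_f <- if (mean_r[1] > mean_r[2]) pair[1]
      else if (mean_r[2] > mean_r[1]) pair[2]
      else sort(pair)[2]  # tie: keep the alphabetically earlier feature
    keep_f <- setdiff(pair, drop_f)
    removed_corr[[length(removed_corr) + 1]] <-
      tibble::tibble(kept = keep_f, removed = drop_f, abs_r = mx)
    keep <- setdiff(keep, drop_f)
    cmat <- cmat[keep, keep, drop = FALSE]
  }
  removed_corr <- if (length(removed_corr) > 0) dplyr::bind_rows(removed_corr)
    else tibble::tibble(kept = character(), removed = character(),
                        abs_r = numeric())
  if (length(keep) < 2)
    abort("fewer than 2 features retained after correlation pruning",
          class = "thetascreen_pipeline_error")

  out <- wells[c(setdiff(names(wells), feats[!feats %in% keep]))]
  structure(out, selection_report = list(
    removed_by_variance = removed_var,
    removed_by_correlation = removed_corr,
    retained = keep
  ))
}

#' @rdname select_features
#' @param x Result of [select_features()].
#' @export
selection_report <- function(x) attr(x, "selection_report")

#' Plate-wise DMSO-referenced normalization
#'
#' Standardizes well profiles plate by plate against that plate's DMSO
#' (negative-control) wells, which removes multiplicative plate effects and
#' the basal morphological differences between cell lines. Per plate and
#' feature: values are divided by the DMSO median (`x' = x / median(DMSO)`),
#' then z-scored with the DMSO mean and standard deviation
#' (`z = (x' - mean(DMSO x')) / sd(DMSO x')`), so the negative control
#' defines the null at zero mean and unit variance on every plate. When the
#' DMSO median of a feature is within a guard epsilon of zero
#' (`1e-9 * (pooled SD + 1)`), the feature is shifted by the median instead
#' of divided, and the guard is recorded. A feature whose DMSO standard
#' deviation is zero on any plate is dropped for the run with a warning.
#' Missing values are imputed with the plate's DMSO median before
#' normalization.
#'
#' @param wells Well-level profile table (after [select_features()]).
#' @param layout Plate map, used to locate each plate's negctrl wells
#'   (ignored if `wells` already carries a `role` column).
#' @param center `"mean"` (the default: classical z-score, DMSO mean exactly
#'   0 and SD exactly 1 per plate) or `"median"` (robust variant: DMSO
#'   median exactly 0, scaled by the DMSO SD about the median). Both remove
#'   multiplicative plate effects exactly.
#' @return Normalized profile tibble with a `"norm_constants"` attribute:
#'   tibble of (`plate`, `feature`, `dmso_median`, `dmso_mean`, `dmso_sd`,
#'   `guarded`) retrievable with [norm_constants()].
#' @export
normalize_to_dmso <- function(wells, layout = NULL,
                              center = c("mean", "median")) {
  center <- match.arg(center)
  if (!"role" %in% names(wells)) {
    if (is.null(layout))
      abort("normalize_to_dmso needs a 'role' column or a plate map",
            class = "thetascreen_config_error")
    wells <- join_layout(wells, layout)
  }
  feats <- feature_cols(wells)
  x <- as.matrix(wells[feats])
  guard <- 1e-9 * (apply(x, 2, sd, na.rm = TRUE) + 1)

  plates <- unique(wells$plate)
  const <- vector("list", length(plates))
  names(const) <- plates
  dead <- character()
  for (p in plates) {
    rows <- which(wells$plate == p)
    neg <- rows[wells$role[rows] == "negctrl"]
    if (length(neg) < 2)
      abort(sprintf("plate %s has < 2 negctrl wells", p),
            class = "thetascreen_layout_error")
    xp <- x[rows, , drop = FALSE]
    med <- apply(x[neg, , drop = FALSE], 2, median, na.rm = TRUE)
    # impute missing values with the plate DMSO median
    for (j in which(colSums(is.na(xp)) > 0))
      xp[is.na(xp[, j]), j] <- med[j]
    guarded <- is.na(med) | abs(med) <= guard
    x1 <- xp
    x1[, !guarded] <- sweep(xp[, !guarded, drop = FALSE], 2, med[!guarded], "/")
    x1[, guarded] <- sweep(xp[, guarded, drop = FALSE], 2, med[guarded], "-")
    neg_local <- match(neg, rows)
    # the scale is the DMSO SD either way (sd is translation-invariant, so
    # the median variant still yields DMSO SD exactly 1)
    s <- apply(x1[neg_local, , drop = FALSE], 2, sd)
    m <- if (center == "mean") colMeans(x1[neg_local, , drop = FALSE])
      else apply(x1[neg_local, , drop = FALSE], 2, median)
    dead <- union(dead, feats[is.na(s) | s == 0])
    z <- sweep(sweep(x1, 2, m, "-"), 2, s, "/")
    x[rows, ] <- z
    const[[p]] <- tibble::tibble(plate = p, feature = feats,
                                 dmso_median = unname(med),
                                 dmso_mean = unname(m), dmso_sd = unname(s),
                                 guarded = unname(guarded))
  }
  if (length(dead) > 0) {
    warn(sprintf("dropping %d feature(s) with zero DMSO variation on some plate: %s",
                 length(dead), paste(head(dead, 5), collapse = ", ")))
    x <- x[, setdiff(feats, dead), drop = FALSE]
    if (ncol(x) < 2)
      abort("fewer than 2 features survive normalization",
            class = "thetascreen_pipeline_error")
  }
  out <- dplyr::bind_cols(wells[setdiff(names(wells), feats)],
                          tibble::as_tibble(x))
  structure(out, norm_constants = dplyr::bind_rows(const))
}

#' @rdname normalize_to_dmso
#' @param x Result of [normalize_to_dmso()].
#' @export
norm_constants <- function(x) attr(x, "norm_constants")
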
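#' Configure a synthetic multi-cell-line morphological screen
#'
#' Builds and validates the configuration for [generate_screen()]. The
#' simulator emulates a Cell Painting-style screen: a panel of cell lines with
#' distinct basal morphologies (distinct feature means, shared low-rank
#' correlation structure), compounds arrayed one-per-well at a single
#' concentration, DMSO negative-control and staurosporine-like
#' positive-control wells on every plate, multiplicative per-plate technical
#' effects, and per-cell sampling noise.
#'
#' Compound effects are displacement vectors in feature space, expressed in
#' units of the per-feature baseline standard deviation. All effect
#' directions lie in the plane spanned by the top two principal axes of the
#' baseline covariance, so the true angle of each cell line's response is a
#' well-defined 2-D quantity commensurate with the theta estimated by
#' [compute_theta()]. By default a compound displaces every cell line in the
#' same direction (true divergence 0); `divergence_spec` plants a chosen
#' angular divergence between a pair of cell lines for chosen compounds.
#'
#' @param n_cell_lines,n_compounds,n_replicates Panel size, library size and
#'   number of screen replicates (each replicate is a fresh set of plates).
#' @param plate_format Wells per plate, 96 or 384.
#' @param n_features Number of morphological features (default 340).
#' @param n_fields_per_well Imaged fields (images) per well.
#' @param cells_per_image_range Integer `(min, max)`; cell count per image is
#'   drawn uniformly from this range.
#' @param frac_inactive Proportion of compounds with no phenotypic effect
#'   (effect magnitude 0 in every cell line).
#' @param effect_magnitude_range `(min, max)` effect magnitude for active
#'   compounds, in baseline-SD units.
#' @param divergence_spec Data frame with columns `compound`, `line_a`,
#'   `line_b`, `angle_deg` (degrees in \[0, 180\]): for each row, the named
#'   compound's effect direction in `line_b` is rotated by `angle_deg`
#'   relative to its direction in `line_a`. Compounds named here are always
#'   active.
#' @param control_layout List with character vectors `negctrl` and `posctrl`
#'   of well names reserved for controls on every plate. Default: plate
#'   column 1 is DMSO, column 2 is the positive control.
#' @param plate_effect_sd SD of the log-normal per-plate, per-feature
#'   multiplicative effect (0 disables plate effects).
#' @param qc_fail_rate Proportion of images degraded to fail default image QC
#'   (see [inject_qc_failures()]).
#' @param pos_effect_magnitude Magnitude of the shared-within-cell-line
#'   positive-control effect, in baseline-SD units.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   screen bit for bit.
#' @return A validated `screen_sim_config` list.
#' @seealso [generate_screen()]
#' @export
screen_sim_config <- function(n_cell_lines = 8,
                              n_compounds = 1280,
                              n_replicates = 1,
                              plate_format = 384,
                              n_features = 340,
                              n_fields_per_well = 1,
                              cells_per_image_range = c(15, 30),
                              frac_inactive = 0.8,
                              effect_magnitude_range = c(2, 6),
                              divergence_spec = NULL,
                              control_layout = NULL,
                              plate_effect_sd = 0.1,
                              qc_fail_rate = 0,
                              pos_effect_magnitude = 20,
                              seed = 1L) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
      abort(sprintf("%s must be a single integer >= %d", nm, min),
            class = "thetascreen_config_error")
    as.integer(x)
  }
  chk_prop <- function(x, nm) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
      abort(sprintf("%s must be in [0, 1]", nm),
            class = "thetascreen_config_error")
    as.numeric(x)
  }
  cfg <- list(
    n_cell_lines = chk_count(n_cell_lines, "n_cell_lines"),
    n_compounds = chk_count(n_compounds, "n_compounds"),
    n_replicates = chk_count(n_replicates, "n_replicates"),
    plate_format = chk_count(plate_format, "plate_format"),
    n_features = chk_count(n_features, "n_features", min = 3),
    n_fields_per_well = chk_count(n_fields_per_well, "n_fields_per_well"),
    cells_per_image_range = c(
      chk_count(cells_per_image_range[1], "cells_per_image_range[1]"),
      chk_count(cells_per_image_range[2], "cells_per_image_range[2]")
    ),
    frac_inactive = chk_prop(frac_inactive, "frac_inactive"),
    effect_magnitude_range = as.numeric(effect_magnitude_range),
    plate_effect_sd = as.numeric(plate_effect_sd),
    qc_fail_rate = chk_prop(qc_fail_rate, "qc_fail_rate"),
    pos_effect_magnitude = as.numeric(pos_effect_magnitude),
    seed = chk_count(seed, "seed", min = 0)
  )
  wells <- plate_wells(cfg$plate_format)
  if (cfg$cells_per_image_range[1] > cfg$cells_per_image_range[2])
    abort("cells_per_image_range must be (min, max) with min <= max",
          class = "thetascreen_config_error")
  if (length(cfg$effect_magnitude_range) != 2 ||
      any(cfg$effect_magnitude_range < 0) ||
      diff(cfg$effect_magnitude_range) < 0)
    abort("effect_magnitude_range must be (min, max) with 0 <= min <= max",
          class = "thetascreen_config_error")
  if (cfg$plate_effect_sd < 0)
    abort("plate_effect_sd must be >= 0", class = "thetascreen_config_error")

  if (is.null(control_layout)) {
    n_rows <- if (cfg$plate_format == 96) 8L else 16L
    control_layout <- list(
      negctrl = wells[seq_len(n_rows)],                # column 1
      posctrl = wells[n_rows + seq_len(n_rows)]        # column 2
    )
  }
  if (!all(c("negctrl", "posctrl") %in% names(control_layout)))
    abort("control_layout needs elements 'negctrl' and 'posctrl'",
          class = "thetascreen_config_error")
  bad <- setdiff(unlist(control_layout), wells)
  if (length(bad) > 0)
    abort(sprintf("control_layout names wells not on a %d-well plate: %s",
                  cfg$plate_format, paste(head(bad, 3), collapse = ", ")),
          class = "thetascreen_layout_error")
  if (length(intersect(control_layout$negctrl, control_layout$posctrl)) > 0)
    abort("negctrl and posctrl wells overlap", class = "thetascreen_layout_error")
  if (length(control_layout$negctrl) < 2 || length(control_layout$posctrl) < 2)
    abort("every plate needs >= 2 negctrl and >= 2 posctrl wells",
          class = "thetascreen_layout_error")
  cfg$control_layout <- control_layout

  cfg$cell_lines <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  cfg$compounds <- sprintf("C%04d", seq_len(cfg$n_compounds))

  if (!is.null(divergence_spec)) {
    divergence_spec <- tibble::as_tibble(divergence_spec)
    assert_cols(divergence_spec, c("compound", "line_a", "line_b", "angle_deg"),
                "divergence_spec")
    unknown_c <- setdiff(divergence_spec$compound, cfg$compounds)
    unknown_l <- setdiff(c(divergence_spec$line_a, divergence_spec$line_b),
                         cfg$cell_lines)
    if (length(unknown_c) > 0 || length(unknown_l) > 0)
      abort(sprintf("divergence_spec references unknown %s",
                    paste(c(
                      if (length(unknown_c)) paste0("compound(s) ",
                        paste(head(unknown_c, 3), collapse = ", ")),
                      if (length(unknown_l)) paste0("cell line(s) ",
                        paste(head(unknown_l, 3), collapse = ", "))
                    ), collapse = "; ")),
            class = "thetascreen_reference_error")
    if (any(divergence_spec$angle_deg < 0 | divergence_spec$angle_deg > 180))
      abort("planted angles must lie in [0, 180] degrees",
            class = "thetascreen_config_error")
    if (any(divergence_spec$line_a == divergence_spec$line_b))
      abort("divergence_spec pairs must name two distinct cell lines",
            class = "thetascreen_config_error")
  }
  cfg$divergence_spec <- divergence_spec
  structure(cfg, class = "screen_sim_config")
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat(sprintf(
    "<screen_sim_config> %d cell lines x %d compounds x %d replicate(s), %d-well plates, %d features\n",
    x$n_cell_lines, x$n_compounds, x$n_replicates, x$plate_format, x$n_features))
  cat(sprintf("  frac_inactive %.2f, effect magnitude %.1f-%.1f SD, plate_effect_sd %.2f, seed %d\n",
              x$frac_inactive, x$effect_magnitude_range[1],
              x$effect_magnitude_range[2], x$plate_effect_sd, x$seed))
  if (!is.null(x$divergence_spec))
    cat(sprintf("  %d planted divergence(s)\n", nrow(x$divergence_spec)))
  invisible(x)
}

# Baseline model shared by all plates of a screen: a 10-factor covariance in
# standardized units, per-feature raw scales, and per-cell-line mean offsets.
# e1/e2 (the top two factor axes) span the plane that carries every compound
# effect direction.
screen_baseline <- function(cfg) {
  f <- cfg$n_features
  n_fac <- min(10L, f)
  basis <- qr.Q(qr(matrix(rnorm(f * n_fac), f, n_fac)))
  lambda <- c(4, 3, rep(1.5, n_fac - 2))[seq_len(n_fac)]
  noise_sd <- 1
  # total baseline SD per feature in standardized units, then raw scale
  std_sd <- sqrt(as.vector(basis^2 %*% lambda^2) + noise_sd^2)
  scale <- exp(rnorm(f, 0, 0.5))
  baseline_sd <- scale * std_sd
  base_mean <- scale * runif(f, 2, 6)
  line_means <- lapply(cfg$cell_lines, function(l) {
    base_mean + 3 * baseline_sd * unitize(rnorm(f))
  })
  names(line_means) <- cfg$cell_lines
  # staurosporine-like effect: one strong direction in the dominant
  # phenotype plane, nearly shared across the panel (small per-line rotation)
  pos_base_angle <- runif(1, 0, 360)
  pos_angles <- (pos_base_angle + rnorm(cfg$n_cell_lines, 0, 15)) %% 360
  pos_dirs <- lapply(pos_angles, function(a) {
    cos(a * pi / 180) * basis[, 1] + sin(a * pi / 180) * basis[, 2]
  })
  names(pos_dirs) <- cfg$cell_lines
  list(basis = basis, lambda = lambda, noise_sd = noise_sd, scale = scale,
       baseline_sd = baseline_sd, line_means = line_means,
       e1 = basis[, 1], e2 = basis[, 2], pos_dirs = pos_dirs)
}

# Per-compound, per-cell-line effect angles (degrees, in the e1/e2 plane) and
# magnitudes (baseline-SD units). Compounds in divergence_spec are active by
# construction.
screen_truth_effects <- function(cfg) {
  n <- cfg$n_compounds
  active <- runif(n) >= cfg$frac_inactive
  forced <- cfg$compounds %in% (cfg$divergence_spec$compound %||% character())
  active <- active | forced
  magnitude <- ifelse(
    active,
    runif(n, cfg$effect_magnitude_range[1], cfg$effect_magnitude_range[2]),
    0
  )
  base_angle <- runif(n, 0, 360)
  angles <- matrix(rep(base_angle, cfg$n_cell_lines), nrow = n,
                   dimnames = list(cfg$compounds, cfg$cell_lines))
  if (!is.null(cfg$divergence_spec)) {
    for (i in seq_len(nrow(cfg$divergence_spec))) {
      row <- cfg$divergence_spec[i, ]
      angles[row$compound, row$line_b] <-
        (angles[row$compound, row$line_a] + row$angle_deg) %% 360
    }
  }
  list(active = setNames(active, cfg$compounds),
       magnitude = setNames(magnitude, cfg$compounds),
       angles = angles)
}

#' Generate a synthetic screen with known ground truth
#'
#' Simulates the full screen described by a [screen_sim_config()]: per-cell
#' feature tables with image QC metrics, a plate map, and the ground truth
#' (per compound x cell line effect angle and magnitude, per-pair true
#' divergence, per-line activity) against which every downstream stage can be
#' validated.
#'
#' Each cell's feature vector is the cell line's baseline mean, plus a draw
#' from the shared low-rank factor covariance, plus the well's compound
#' effect (on the raw feature scale), all multiplied by the plate's
#' log-normal technical effect. Positive-control wells receive a fixed large
#' effect vector shared within each cell line; negative controls receive no
#' effect. When `qc_fail_rate > 0`, [inject_qc_failures()] is applied before
#' returning.
#'
#' @param config A [screen_sim_config()].
#' @return A `theta_screen` list with elements `cells` (per-cell
#'   CellFeatureTable), `layout` (plate map), `truth` (see
#'   [truth_pair_angles()], [truth_effect_vectors()]) and `config`.
#' @examples
#' scr <- generate_screen(screen_sim_config(
#'   n_cell_lines = 2, n_compounds = 8, plate_format = 96,
#'   n_features = 20, seed = 7))
#' dplyr::count(scr$layout, role)
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  withr::with_seed(config$seed, generate_screen_impl(config))
}

generate_screen_impl <- function(cfg) {
  base <- screen_baseline(cfg)
  fx <- screen_truth_effects(cfg)
  f <- cfg$n_features
  feat_names <- sprintf("feat_%03d", seq_len(f))
  wells <- plate_wells(cfg$plate_format)
  ctrl <- cfg$control_layout
  treat_wells <- setdiff(wells, c(ctrl$negctrl, ctrl$posctrl))
  n_treat <- length(treat_wells)
  n_plates <- ceiling(cfg$n_compounds / n_treat)

  # effect vectors in raw units: magnitude * baseline_sd (x) unit direction
  effect_raw <- function(line, angle_deg, magnitude) {
    th <- angle_deg * pi / 180
    dir <- cos(th) * base$e1 + sin(th) * base$e2
    magnitude * base$baseline_sd * dir
  }

  layout_list <- list()
  cell_list <- list()
  for (line in cfg$cell_lines) {
    for (rep_id in seq_len(cfg$n_replicates)) {
      for (p in seq_len(n_plates)) {
        barcode <- sprintf("%s_R%d_P%02d", line, rep_id, p)
        cmpd_idx <- ((p - 1) * n_treat + 1):min(p * n_treat, cfg$n_compounds)
        cmpds <- cfg$compounds[cmpd_idx]
        used_treat <- treat_wells[seq_along(cmpds)]
        lay <- tibble::tibble(
          plate = barcode,
          well = c(ctrl$negctrl, ctrl$posctrl, used_treat),
          compound = c(rep("DMSO", length(ctrl$negctrl)),
                       rep("staurosporine", length(ctrl$posctrl)),
                       cmpds),
          conc = c(rep("0.1%", length(ctrl$negctrl)),
                   rep("0.3uM", length(ctrl$posctrl)),
                   rep("1uM", length(cmpds))),
          role = c(rep("negctrl", length(ctrl$negctrl)),
                   rep("posctrl", length(ctrl$posctrl)),
                   rep("treatment", length(cmpds))),
          cell_line = line,
          replicate = rep_id
        )
        layout_list[[barcode]] <- lay

        # per-well raw effect vectors
        eff <- matrix(0, nrow(lay), f)
        pos_rows <- which(lay$role == "posctrl")
        if (length(pos_rows) > 0)
          eff[pos_rows, ] <- matrix(
            cfg$pos_effect_magnitude * base$baseline_sd * base$pos_dirs[[line]],
            length(pos_rows), f, byrow = TRUE)
        tr_rows <- which(lay$role == "treatment")
        for (i in tr_rows) {
          cm <- lay$compound[i]
          if (fx$magnitude[cm] > 0)
            eff[i, ] <- effect_raw(line, fx$angles[cm, line], fx$magnitude[cm])
        }

        plate_mult <- exp(rnorm(f, 0, cfg$plate_effect_sd))
        n_images_per_well <- cfg$n_fields_per_well
        n_images <- nrow(lay) * n_images_per_well
        rng <- cfg$cells_per_image_range
        cells_per_image <- rng[1] +
          sample.int(rng[2] - rng[1] + 1L, n_images, replace = TRUE) - 1L
        well_of_image <- rep(seq_len(nrow(lay)), each = n_images_per_well)
        field_of_image <- rep(seq_len(n_images_per_well), nrow(lay))
        n_cells <- sum(cells_per_image)
        img_of_cell <- rep(seq_len(n_images), cells_per_image)

        n_fac <- ncol(base$basis)
        eta <- matrix(rnorm(n_cells * n_fac), n_cells, n_fac)
        dev <- eta %*% (t(base$basis) * base$lambda) +
          matrix(rnorm(n_cells * f, 0, base$noise_sd), n_cells, f)
        dev <- dev * rep(base$scale, each = n_cells)
        x <- dev + matrix(base$line_means[[line]], n_cells, f, byrow = TRUE) +
          eff[well_of_image[img_of_cell], , drop = FALSE]
        x <- x * rep(plate_mult, each = n_cells)
        colnames(x) <- feat_names

        image_ids <- sprintf("%s_%s_f%02d", barcode,
                             lay$well[well_of_image], field_of_image)
        qc_sat <- runif(n_images, 0, 0.05)
        qc_foc <- abs(rnorm(n_images, 100, 3))
        dt <- data.table::data.table(
          plate = barcode,
          well = lay$well[well_of_image[img_of_cell]],
          image_id = image_ids[img_of_cell],
          object_id = unlist(lapply(cells_per_image, seq_len), use.names = FALSE),
          qc_saturation = qc_sat[img_of_cell],
          qc_focus = qc_foc[img_of_cell]
        )
        cell_list[[barcode]] <- cbind(dt, data.table::as.data.table(x))
      }
    }
  }

  cells <- tibble::as_tibble(data.table::rbindlist(cell_list))
  layout <- dplyr::bind_rows(layout_list)

  truth <- list(
    compounds = tibble::tibble(
      compound = cfg$compounds,
      magnitude = unname(fx$magnitude),
      active = unname(fx$magnitude > 0)
    ),
    effects = tidyr::expand_grid(compound = cfg$compounds,
                                 cell_line = cfg$cell_lines) |>
      dplyr::mutate(
        angle_deg = fx$angles[cbind(.data$compound, .data$cell_line)],
        magnitude = fx$magnitude[.data$compound],
        active = .data$magnitude > 0
      ),
    basis = cbind(e1 = base$e1, e2 = base$e2),
    baseline_sd = setNames(base$baseline_sd, feat_names),
    pos_dirs = base$pos_dirs,
    qc_failed_images = character()
  )

  scr <- structure(list(cells = cells, layout = layout, truth = truth,
                        config = cfg),
                   class = "theta_screen")
  if (cfg$qc_fail_rate > 0) scr <- inject_qc_failures(scr, cfg)
  scr
}

#' @export
print.theta_screen <- function(x, ...) {
  cat(sprintf("<theta_screen> %d cells, %d wells on %d plates, %d features\n",
              nrow(x$cells), nrow(x$layout),
              length(unique(x$layout$plate)), length(feature_cols(x$cells))))
  cat(sprintf("  %d/%d compounds active in ground truth; %d QC-failed image(s)\n",
              sum(x$truth$compounds$active), nrow(x$truth$compounds),
              length(x$truth$qc_failed_images)))
  invisible(x)
}

#' True divergence angle for every compound and cell-line pair
#'
#' The planted angular divergence between the two cell lines' effect
#' directions, computed from the ground-truth angles with wrap-around; it is
#' symmetric in the pair and lies in \[0, 180\]. Pairs are reported with
#' `line_a < line_b`.
#'
#' @param truth The `truth` element of a [generate_screen()] result.
#' @return Tibble with columns `compound`, `line_a`, `line_b`, `angle_deg`,
#'   `active`.
#' @export
truth_pair_angles <- function(truth) {
  eff <- truth$effects
  dplyr::inner_join(
    eff, eff,
    by = c("compound", "magnitude", "active"),
    suffix = c("_a", "_b"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$cell_line_a < .data$cell_line_b) |>
    dplyr::transmute(
      compound = .data$compound,
      line_a = .data$cell_line_a,
      line_b = .data$cell_line_b,
      angle_deg = angle_diff(.data$angle_deg_a, .data$angle_deg_b),
      active = .data$active
    )
}

#' Materialise ground-truth effect vectors in feature space
#'
#' Reconstructs the standardized-scale effect vector (magnitude times unit
#' direction in the planted 2-D plane) for each compound x cell line from the
#' stored basis and angles.
#'
#' @param truth The `truth` element of a [generate_screen()] result.
#' @param compounds,cell_lines Optional subsets.
#' @return A matrix with one row per compound x cell line (rownames
#'   `"compound.cell_line"`) and one column per feature.
#' @export
truth_effect_vectors <- function(truth, compounds = NULL, cell_lines = NULL) {
  eff <- truth$effects
  if (!is.null(compounds)) eff <- dplyr::filter(eff, .data$compound %in% compounds)
  if (!is.null(cell_lines)) eff <- dplyr::filter(eff, .data$cell_line %in% cell_lines)
  th <- eff$angle_deg * pi / 180
  v <- outer(eff$magnitude * cos(th), truth$basis[, "e1"]) +
    outer(eff$magnitude * sin(th), truth$basis[, "e2"])
  rownames(v) <- paste(eff$compound, eff$cell_line, sep = ".")
  v
}

#' Degrade a fraction of images so they fail default QC
#'
#' Each image is independently flagged with probability `qc_fail_rate`.
#' Flagged images get a saturation fraction drawn above the default
#' saturation cutoff; a random half additionally get a near-zero focus score.
#' Flagged image ids are recorded (in `truth$qc_failed_images` when a full
#' `theta_screen` is passed, or as the `"qc_failed_images"` attribute when a
#' plain cell table is passed) so the removal performed later by
#' [qc_filter_images()] can be checked exactly.
#'
#' @param x A `theta_screen` from [generate_screen()], or a cell-level
#'   feature table with `qc_saturation`/`qc_focus` columns.
#' @param config The [screen_sim_config()] supplying `qc_fail_rate`; the
#'   injection uses its own seed stream derived from `config$seed`.
#' @return Same type as `x`, with degraded QC metrics.
#' @export
inject_qc_failures <- function(x, config) {
  stopifnot(inherits(config, "screen_sim_config"))
  cells <- if (inherits(x, "theta_screen")) x$cells else x
  assert_cols(cells, c("image_id", "qc_saturation", "qc_focus"), "cell table")
  inj_seed <- as.integer((as.numeric(config$seed) + 104729) %% 2147483647)
  res <- withr::with_seed(inj_seed, {
    imgs <- unique(cells$image_id)
    flagged <- imgs[runif(length(imgs)) < config$qc_fail_rate]
    sat <- runif(length(flagged), 0.6, 1)
    foc_too <- runif(length(flagged)) < 0.5
    foc <- runif(length(flagged), 0, 1)
    idx <- match(cells$image_id, flagged)
    hit <- !is.na(idx)
    cells$qc_saturation[hit] <- sat[idx[hit]]
    hit_foc <- hit & foc_too[idx]
    cells$qc_focus[hit_foc] <- foc[idx[hit_foc]]
    list(cells = cells, flagged = flagged)
  })
  if (inherits(x, "theta_screen")) {
    x$cells <- res$cells
    x$truth$qc_failed_images <- res$flagged
    x
  } else {
    structure(res$cells, qc_failed_images = res$flagged)
  }
}

#' Write a simulated screen to disk
#'
#' Generates the screen and writes the cell-level feature table and plate map
#' in the generic CSV dialect read back by [read_feature_table()] and
#' [read_plate_layout()], the ground truth (per compound x line effects,
#' per-pair true angles, and the 2-D effect basis) as CSVs, and the
#' configuration as YAML.
#'
#' @param config A [screen_sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the `theta_screen` object.
#' @export
simulate_screen <- function(config, dir) {
  scr <- generate_screen(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(scr$cells, file.path(dir, "cells.csv"))
  readr::write_csv(scr$layout, file.path(dir, "plate_map.csv"))
  readr::write_csv(scr$truth$effects, file.path(dir, "truth_effects.csv"))
  readr::write_csv(truth_pair_angles(scr$truth),
                   file.path(dir, "truth_pair_angles.csv"))
  readr::write_csv(
    tibble::tibble(feature = names(scr$truth$baseline_sd),
                   e1 = scr$truth$basis[, "e1"], e2 = scr$truth$basis[, "e2"],
                   baseline_sd = unname(scr$truth$baseline_sd)),
    file.path(dir, "truth_basis.csv"))
  if (length(scr$truth$qc_failed_images) > 0)
    readr::write_csv(tibble::tibble(image_id = scr$truth$qc_failed_images),
                     file.path(dir, "truth_qc_failed_images.csv"))
  cfg_out <- scr$config
  cfg_out$divergence_spec <- if (!is.null(cfg_out$divergence_spec))
    as.list(as.data.frame(cfg_out$divergence_spec))
  yaml::write_yaml(unclass(cfg_out), file.path(dir, "screen_config.yaml"))
  invisible(scr)
}
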
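# Shared fixture builders and independent oracles.

# a small screen config used across tests (fast: ~20k cells)
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_cell_lines = 2, n_compounds = 16, n_replicates = 1,
         plate_format = 96, n_features = 20, cells_per_image_range = c(5, 10),
         frac_inactive = 0.5, seed = 7),
    list(...))
  do.call(screen_sim_config, args)
}

# hand-built cell table: n objects per image, deterministic values
toy_cells <- function() {
  tibble::tibble(
    plate = "P1",
    well = rep(c("A01", "A02"), each = 3),
    image_id = rep(c("img1", "img2"), each = 3),
    object_id = rep(1:3, 2),
    qc_saturation = 0.01,
    qc_focus = 100,
    f1 = c(1, 2, 9, 4, 5, 6),
    f2 = c(10, 20, 30, 40, 50, 60)
  )
}

# centered-PC-style table from a coordinate matrix
toy_centered <- function(coords, compound = NULL, cell_line = "CL01",
                         replicate = 1L, role = "treatment") {
  coords <- as.matrix(coords)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  if (is.null(compound)) compound <- sprintf("C%04d", seq_len(nrow(coords)))
  dplyr::bind_cols(
    tibble::tibble(plate = "P1", well = sprintf("W%03d", seq_len(nrow(coords))),
                   compound = compound, cell_line = cell_line,
                   replicate = replicate, role = role),
    tibble::as_tibble(coords)
  )
}

# independent angle oracle: arccos of cosine similarity between 2-D vectors,
# in degrees
oracle_angle_2d <- function(a, b) {
  ca <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

# brute-force rank product: matrix of delta values (items x replicates)
oracle_rank_product <- function(mat) {
  ranks <- apply(mat, 2, function(col) rank(-col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = nrow(mat))
  apply(ranks, 1, function(r) prod(r)^(1 / length(r)))
}

# minimal wells + layout pair for preprocess tests: one cell line, plates
# with negctrl/posctrl/treatment wells and feature values supplied by `fill`
toy_wells <- function(n_feat = 4, plates = "P1", n_treat = 4, fill = NULL,
                      seed = 1) {
  set.seed(seed)
  wl <- list()
  lay <- list()
  for (p in plates) {
    wells <- sprintf("A%02d", seq_len(4 + n_treat))
    roles <- c("negctrl", "negctrl", "posctrl", "posctrl",
               rep("treatment", n_treat))
    x <- if (is.null(fill)) matrix(rnorm(length(wells) * n_feat, 10, 2),
                                   length(wells), n_feat)
      else fill(p, length(wells), n_feat)
    colnames(x) <- sprintf("feat_%02d", seq_len(n_feat))
    wl[[p]] <- dplyr::bind_cols(
      tibble::tibble(plate = p, well = wells, n_images = 1L),
      tibble::as_tibble(x))
    lay[[p]] <- tibble::tibble(
      plate = p, well = wells,
      compound = ifelse(roles == "treatment", paste0("C", seq_along(wells)),
                        ifelse(roles == "negctrl", "DMSO", "STS")),
      conc = "1uM", role = roles, cell_line = "CL01", replicate = 1L)
  }
  list(wells = dplyr::bind_rows(wl), layout = dplyr::bind_rows(lay))
}
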
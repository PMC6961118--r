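test_that("feature tables are read and typed under both dialects", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plate,well,image_id,object_id,f1,f2",
    "P1,A01,i1,1,1.5,2",
    "P1,A01,i1,2,2.5,oops",
    "P1,A02,i2,1,3.5,4"
  ), tf)
  tab <- read_feature_table(tf)
  expect_equal(nrow(tab), 3)
  expect_setequal(feature_cols(tab), c("f1", "f2"))
  expect_true(is.na(tab$f2[2]))  # non-numeric cell becomes missing

  cp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Metadata_Plate,Metadata_Well,ImageNumber,ObjectNumber,AreaShape_Area",
    "P1,A01,1,1,120.5",
    "P1,A01,1,2,98.0"
  ), cp)
  tab2 <- read_feature_table(cp, dialect = "cellprofiler")
  expect_named(tab2, c("plate", "well", "image_id", "object_id",
                       "AreaShape_Area"))
  expect_equal(feature_cols(tab2), "AreaShape_Area")
})

test_that("malformed feature tables fail with informative errors", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate,image_id,object_id,f1", "P1,i1,1,2"), tf)
  expect_error(read_feature_table(tf), "well",
               class = "thetascreen_format_error")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("plate,well,image_id,object_id,f1", empty)
  expect_error(read_feature_table(empty), "empty",
               class = "thetascreen_format_error")

  expect_error(read_feature_table(tf, dialect = "nope"),
               class = "thetascreen_config_error")
})

test_that("rows with missing identifiers are rejected and counted", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plate,well,image_id,object_id,f1",
    "P1,A01,i1,1,1",
    "P1,,i1,2,2",
    "P1,A01,i1,3,3"
  ), tf)
  expect_message(tab <- read_feature_table(tf), "rejected 1")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_rejected"), 1L)
})

test_that("plate maps validate against the feature table", {
  lay <- tibble::tibble(
    plate = "P1", well = c("A01", "A02", "A03", "A04", "A05"),
    compound = c("DMSO", "DMSO", "STS", "STS", "C1"),
    conc = "x", role = c("negctrl", "negctrl", "posctrl", "posctrl",
                         "treatment"),
    cell_line = "CL01", replicate = 1L)
  cells <- toy_cells()
  expect_silent(validate_layout(cells, lay))

  # a well in the data but not the map fails loudly
  cells_bad <- dplyr::mutate(cells, well = ifelse(well == "A02", "B09", well))
  expect_error(validate_layout(cells_bad, lay), "absent",
               class = "thetascreen_layout_error")
  # duplicated map entry
  expect_error(validate_layout(cells, dplyr::bind_rows(lay, lay[1, ])),
               "more than once", class = "thetascreen_layout_error")
  # too few controls
  expect_error(validate_layout(cells, lay[c(1, 3, 4, 5), ]),
               class = "thetascreen_layout_error")
  # join is total or fails
  expect_error(join_layout(cells_bad, lay),
               class = "thetascreen_layout_error")
  joined <- join_layout(cells, lay)
  expect_true(all(!is.na(joined$role)))
})

test_that("saturated and out-of-focus images are removed with reasons", {
  cells <- toy_cells()
  cells$qc_saturation[cells$image_id == "img2"] <- 1.0
  out <- qc_filter_images(cells, sat_max = 0.2, focus_min = 0)
  expect_setequal(unique(out$image_id), "img1")
  expect_equal(qc_report(out)$reason, "saturation")

  # all images pass: output identical to input
  clean <- toy_cells()
  out2 <- qc_filter_images(clean, sat_max = 0.2, focus_min = 0)
  expect_equal(tibble::as_tibble(out2), clean, ignore_attr = TRUE)
  expect_equal(nrow(qc_report(out2)), 0)

  # explicit focus threshold
  foc <- toy_cells()
  foc$qc_focus[foc$image_id == "img1"] <- 1
  out3 <- qc_filter_images(foc, sat_max = 0.2, focus_min = 50)
  expect_setequal(unique(out3$image_id), "img2")
  expect_equal(qc_report(out3)$reason, "focus")

  # QC metrics absent -> configuration error
  expect_error(qc_filter_images(dplyr::select(clean, -qc_focus)),
               class = "thetascreen_config_error")
})

test_that("median aggregation matches hand-computed values", {
  cells <- toy_cells()  # img1: f1 = 1,2,9; img2: f1 = 4,5,6
  img <- aggregate_to_image_median(cells)
  expect_equal(img$f1[img$image_id == "img1"], 2)
  expect_equal(img$f1[img$image_id == "img2"], 5)
  expect_equal(img$n_objects, c(3L, 3L))

  # even-count median is the mean of the middle pair
  even <- tibble::tibble(plate = "P1", well = "A01", image_id = "i",
                         object_id = 1:4, f1 = c(1, 2, 3, 100))
  expect_equal(aggregate_to_image_median(even)$f1, 2.5)

  # single object: image profile equals the object
  one <- tibble::tibble(plate = "P1", well = "A01", image_id = "i",
                        object_id = 1L, f1 = 42, f2 = -1)
  expect_equal(aggregate_to_image_median(one)$f1, 42)
  expect_equal(aggregate_to_image_median(one)$f2, -1)

  # well roll-up: median of image medians, n_images recorded
  img2 <- tibble::tibble(plate = "P1", well = "A01", image_id = c("i1", "i2"),
                         f1 = c(2, 4))
  w <- aggregate_to_well(img2)
  expect_equal(w$f1, 3)
  expect_equal(w$n_images, 2L)
  # one image per well: identity
  expect_equal(aggregate_to_well(img2[1, ])$f1, 2)
})

test_that("aggregation is permutation-invariant and commutes with QC filtering", {
  cells <- generate_screen(tiny_config())$cells
  set.seed(1)
  shuffled <- cells[sample(nrow(cells)), ]
  expect_equal(aggregate_to_image_median(cells),
               aggregate_to_image_median(shuffled))

  # image-keyed filtering commutes with aggregation over objects
  cells$qc_saturation[cells$image_id %in% unique(cells$image_id)[1:5]] <- 0.9
  path1 <- aggregate_to_image_median(
    qc_filter_images(cells, sat_max = 0.2, focus_min = 0))
  pre <- aggregate_to_image_median(cells)
  keep <- dplyr::distinct(cells, image_id, qc_saturation, qc_focus)
  pre <- dplyr::semi_join(
    pre, dplyr::filter(keep, qc_saturation <= 0.2), by = "image_id")
  expect_equal(path1[feature_cols(path1)], pre[feature_cols(pre)])
})

test_that("a QC-removed field drops out of the well median", {
  # 4 fields with values 1,2,3,100; removing the saturated 100-field leaves
  # the median of 1,2,3
  cells <- tibble::tibble(
    plate = "P1", well = "A01",
    image_id = paste0("f", 1:4), object_id = 1L,
    qc_saturation = c(0.01, 0.01, 0.01, 0.95), qc_focus = 100,
    f1 = c(1, 2, 3, 100))
  filtered <- qc_filter_images(cells, sat_max = 0.2, focus_min = 0)
  w <- aggregate_to_well(aggregate_to_image_median(filtered))
  expect_equal(w$f1, 2)
  expect_equal(w$n_images, 3L)
})
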
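theta_of <- function(x, y) {
  cen <- toy_centered(rbind(c(x, y)))
  compute_theta(cen)$theta_deg
}

test_that("theta is the counter-clockwise plane angle in [0, 360)", {
  expect_equal(theta_of(1, 0), 0)
  expect_equal(theta_of(0, 1), 90)
  expect_equal(theta_of(-1, -1), 225)
  expect_equal(theta_of(1, -1), 315)
  th <- compute_theta(toy_centered(rbind(c(3, -4))))
  expect_equal(th$magnitude, 5)
})

test_that("theta is undefined for zero magnitude, floors and inactive calls", {
  cen <- toy_centered(rbind(c(0, 0), c(5, 0), c(0.5, 0)))
  th <- compute_theta(cen)
  expect_false(th$theta_defined[1])
  expect_true(is.na(th$theta_deg[1]))

  th2 <- compute_theta(cen, magnitude_floor = 1)
  expect_equal(th2$theta_defined, c(FALSE, TRUE, FALSE))

  act <- tibble::tibble(compound = sprintf("C%04d", 1:3), cell_line = "CL01",
                        active = c(TRUE, FALSE, TRUE))
  th3 <- compute_theta(cen, activity = act)
  expect_equal(th3$theta_defined, c(FALSE, FALSE, TRUE))

  expect_error(compute_theta(toy_centered(matrix(1, 2, 1))),
               class = "thetascreen_pipeline_error")
})

test_that("delta theta wraps around and is symmetric in the pair", {
  mk <- function(tA, tB) {
    rad <- c(tA, tB) * pi / 180
    dplyr::bind_rows(
      toy_centered(rbind(c(cos(rad[1]), sin(rad[1]))), compound = "C1",
                   cell_line = "CL01"),
      toy_centered(rbind(c(cos(rad[2]), sin(rad[2]))), compound = "C1",
                   cell_line = "CL02"))
  }
  dt <- function(tA, tB) delta_theta(compute_theta(mk(tA, tB)))$delta_theta_deg
  expect_equal(dt(0, 90), 90)
  expect_equal(dt(350, 10), 20)
  expect_equal(dt(45, 225), 180)
  expect_equal(dt(10, 350), dt(350, 10))
  expect_equal(dt(33, 33), 0)
})

test_that("theta/delta-theta equal the arccos-cosine oracle on random vectors", {
  set.seed(11)
  n <- 1000
  a <- matrix(rnorm(2 * n), n, 2)
  b <- matrix(rnorm(2 * n), n, 2)
  impl <- angle_diff((atan2(a[, 2], a[, 1]) * 180 / pi) %% 360,
                     (atan2(b[, 2], b[, 1]) * 180 / pi) %% 360)
  oracle <- vapply(seq_len(n), function(i) oracle_angle_2d(a[i, ], b[i, ]),
                   numeric(1))
  expect_lt(max(abs(impl - oracle)), 1e-9)
})

test_that("delta theta is a pseudometric on directions", {
  set.seed(12)
  th <- matrix(runif(300 * 3, 0, 360), ncol = 3)
  d12 <- angle_diff(th[, 1], th[, 2])
  d23 <- angle_diff(th[, 2], th[, 3])
  d13 <- angle_diff(th[, 1], th[, 3])
  expect_true(all(d13 <= d12 + d23 + 1e-9))       # triangle inequality
  expect_true(all(d12 >= 0 & d12 <= 180))
  expect_equal(angle_diff(th[, 1], th[, 1]), rep(0, nrow(th)))
})

test_that("global plane rotations leave delta theta unchanged", {
  set.seed(13)
  n_rot <- 100
  v <- matrix(rnorm(2 * 40), 40, 2)
  base <- angle_diff((atan2(v[1:20, 2], v[1:20, 1]) * 180 / pi) %% 360,
                     (atan2(v[21:40, 2], v[21:40, 1]) * 180 / pi) %% 360)
  for (r in seq_len(n_rot)) {
    th <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    vr <- v %*% t(rot)
    rotated <- angle_diff((atan2(vr[1:20, 2], vr[1:20, 1]) * 180 / pi) %% 360,
                          (atan2(vr[21:40, 2], vr[21:40, 1]) * 180 / pi) %% 360)
    expect_lt(max(abs(rotated - base)), 1e-9)
  }
})

test_that("rank products match hand computation, including fractional ties", {
  dts <- tibble::tibble(
    compound = rep(c("A", "B", "C"), times = 3),
    line_a = "CL01", line_b = "CL02",
    replicate = rep(1:3, each = 3),
    delta_theta_deg = c(170, 20, 90,   # rep1 ranks: A=1, C=2, B=3
                        20, 90, 170,   # rep2 ranks: C=1, B=2, A=3
                        90, 20, 170))  # rep3 ranks: C=1, A=2, B=3
  rp <- rank_product(dts)
  # A: ranks 1,3,2 -> (6)^(1/3); B: 3,2,3 -> 18^(1/3); C: 2,1,1 -> 2^(1/3)
  expect_equal(rp$rank_product[rp$compound == "A"], 6^(1/3), tolerance = 1e-12)
  expect_equal(rp$rank_product[rp$compound == "B"], 18^(1/3), tolerance = 1e-12)
  expect_equal(rp$rank_product[rp$compound == "C"], 2^(1/3), tolerance = 1e-12)
  expect_equal(rp$compound, c("C", "A", "B"))
  expect_equal(rp$final_rank, 1:3)
  # matches the brute-force oracle
  mat <- matrix(dts$delta_theta_deg, nrow = 3)[order(c("A", "B", "C")), ]
  expect_equal(sort(rp$rank_product), sort(oracle_rank_product(mat)),
               tolerance = 1e-12)

  # RP of ranks [1, 4, 2] is exactly 2
  expect_equal(exp(mean(log(c(1, 4, 2)))), 2, tolerance = 1e-12)

  # ties within a replicate get fractional average ranks
  tie <- tibble::tibble(compound = c("A", "B", "C"), line_a = "x",
                        line_b = "y", replicate = 1,
                        delta_theta_deg = c(150, 150, 10))
  rp_tie <- rank_product(tie)
  expect_equal(sort(rp_tie$rank_product[rp_tie$compound %in% c("A", "B")]),
               c(1.5, 1.5))

  # single replicate: rank product equals the rank
  single <- dplyr::filter(dts, replicate == 1)
  rp1 <- rank_product(single)
  expect_equal(rp1$rank_product, c(1, 2, 3))
  expect_equal(rp1$compound, c("A", "C", "B"))
})

test_that("rank product ordering is invariant to replicate order and monotone rescaling", {
  set.seed(14)
  dts <- tidyr::expand_grid(compound = sprintf("C%02d", 1:10),
                            line_a = "CL01", line_b = "CL02",
                            replicate = 1:3) |>
    dplyr::mutate(delta_theta_deg = runif(dplyr::n(), 0, 180))
  rp <- rank_product(dts)
  # shuffle replicate labels
  relab <- dplyr::mutate(dts, replicate = c(3, 1, 2)[replicate])
  expect_equal(rank_product(relab)$compound, rp$compound)
  # strictly monotone transform of delta within every replicate
  trans <- dplyr::mutate(dts, delta_theta_deg = delta_theta_deg^3 / 100 + 1)
  expect_equal(rank_product(trans)$compound, rp$compound)
  expect_equal(rank_product(trans)$rank_product, rp$rank_product)
})

test_that("items missing a replicate and undefined deltas are excluded, reported", {
  dts <- tidyr::expand_grid(compound = c("A", "B"), line_a = "x", line_b = "y",
                            replicate = 1:2) |>
    dplyr::mutate(delta_theta_deg = c(100, 50, NA, 60))  # B lacks replicate 1
  expect_message(expect_warning(rp <- rank_product(dts), "excluded"),
                 "undefined")
  expect_equal(rp$compound, "A")
  expect_equal(rp$rank_product, 1)
})

test_that("hit lists honour pan-activity, exclusions and truncation", {
  rp <- tibble::tibble(final_rank = 1:3, compound = c("A", "B", "C"),
                       line_a = "x", line_b = "y",
                       mean_delta_theta = c(170, 120, 80),
                       rank_product = 1:3)
  act <- tidyr::expand_grid(compound = c("A", "B", "C"),
                            cell_line = c("x", "y")) |>
    dplyr::mutate(active = compound != "B", l1_distance = 1, threshold = 0)
  hits <- build_hit_list(rp, activity = act)
  expect_equal(hits$compound, c("A", "C"))
  expect_equal(hits$final_rank, 1:2)

  # excluding the rank-1 compound promotes the next
  hits2 <- build_hit_list(rp, exclude = "A")
  expect_equal(hits2$compound[1], "B")
  expect_equal(hits2$final_rank[1], 1)
  expect_warning(build_hit_list(rp, exclude = "ZZZ"), "unknown")

  # top_n larger than the table returns the full table
  expect_equal(nrow(build_hit_list(rp, top_n = 100)), 3)
  expect_equal(nrow(build_hit_list(rp, top_n = 2)), 2)
})

test_that("the k-dimensional angle variant agrees with 2-D when k = 2", {
  set.seed(15)
  cen <- dplyr::bind_rows(
    toy_centered(matrix(rnorm(20), 10, 2), cell_line = "CL01"),
    toy_centered(matrix(rnorm(20), 10, 2), cell_line = "CL02"))
  d2 <- delta_theta(compute_theta(cen))
  dk <- delta_theta_kd(cen)
  merged <- dplyr::inner_join(d2, dk, by = c("compound", "line_a", "line_b",
                                             "replicate"))
  expect_lt(max(abs(merged$delta_theta_deg.x - merged$delta_theta_deg.y)),
            1e-9)
})
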
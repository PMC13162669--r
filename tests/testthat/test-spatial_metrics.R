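test_that("nearest-neighbor distances: worked geometry and empty targets", {
  region <- make_region(tam = rbind(c(0, 0)),
                        cd8 = rbind(c(3, 4), c(10, 0)))
  d <- nearest_neighbor_distances(region, "PDL1_TAM", "CD8_T")
  expect_equal(d, 5)  # min of {5, 10}: the 3-4-5 triangle wins
  # directional: each CD8's nearest TAM
  expect_equal(nearest_neighbor_distances(region, "CD8_T", "PDL1_TAM"),
               c(5, 10))
  # no CD8 at all -> every TAM entry undefined
  only_tam <- make_region(tam = rbind(c(1, 1), c(2, 2)))
  expect_equal(nearest_neighbor_distances(only_tam, "PDL1_TAM", "CD8_T"),
               c(NA_real_, NA_real_))
  expect_error(nearest_neighbor_distances(region, "CD8_T", "B_CELL"),
               "unknown phenotype")
})

test_that("accelerated neighbor search equals the brute-force scan exactly", {
  set.seed(101)
  for (i in 1:25) {
    region <- random_region(sample(0:60, 1), sample(0:120, 1),
                            sample(0:100, 1))
    src <- cells_xy(region, "CD8_T"); tgt <- cells_xy(region, "PDL1_TAM")
    expect_identical(nearest_neighbor_distances(region, "CD8_T", "PDL1_TAM"),
                     brute_nn(src$x, src$y, tgt$x, tgt$y))
  }
})

test_that("median_nn_distance follows the stated conventions", {
  expect_equal(median_nn_distance(c(5, 13, 40)), 13)
  expect_equal(median_nn_distance(c(10, 20)), 15)
  expect_equal(median_nn_distance(c(7, NA, 9, NA)), 8)
  expect_true(is.na(median_nn_distance(c(NA_real_, NA_real_))))
  expect_true(is.na(median_nn_distance(numeric())))
})

test_that("count_cd8_within: worked geometry, boundary and at-least-one semantics", {
  region <- make_region(
    tam = rbind(c(0, 0), c(100, 0)),
    cd8 = rbind(c(0, 20), c(0, 24), c(60, 0), c(100, 30)))
  # (60,0) is 40 from its nearest TAM; (100,30) is 30: both out at r = 25
  expect_equal(count_cd8_within(region, 25), 2)
  # boundary convention: a CD8 at exactly r
  edge <- make_region(tam = rbind(c(0, 0)), cd8 = rbind(c(0, 25)))
  expect_equal(count_cd8_within(edge, 25, boundary_inclusive = TRUE), 1)
  expect_equal(count_cd8_within(edge, 25, boundary_inclusive = FALSE), 0)
  # a CD8 near three TAMs still contributes once
  multi <- make_region(tam = rbind(c(0, 0), c(5, 0), c(0, 5)),
                       cd8 = rbind(c(2, 2)))
  expect_equal(count_cd8_within(multi, 25), 1)
})

test_that("interaction_variable normalizes and handles degenerate regions", {
  cfg <- proximity_config()
  # 10 TAMs and 10 CD8 all coincident -> all within -> iv = 100*10/20
  both <- make_region(tam = cbind(rep(1, 10), rep(1, 10)),
                      cd8 = cbind(rep(2, 10), rep(2, 10)))
  expect_equal(interaction_variable(both, cfg)$iv, 50)
  # worked geometry: 2 TAMs, 4 CD8, 2 within
  geom <- make_region(tam = rbind(c(0, 0), c(100, 0)),
                      cd8 = rbind(c(0, 20), c(0, 24), c(60, 0), c(100, 30)))
  res <- interaction_variable(geom, cfg)
  expect_equal(res$n_cd8_within, 2L)
  expect_equal(res$iv, 100 * 2 / 6)
  # TAMs without CD8: defined zero
  tam_only <- make_region(tam = cbind(runif(5, 0, 10), runif(5, 0, 10)))
  expect_equal(interaction_variable(tam_only, cfg)$iv, 0)
  # CD8 without TAMs: defined zero (no interaction observable)
  cd8_only <- make_region(cd8 = rbind(c(1, 1), c(2, 2)))
  expect_equal(interaction_variable(cd8_only, cfg)$iv, 0)
  # neither phenotype: undefined, not zero
  other_only <- make_region(other = rbind(c(1, 1)))
  expect_true(is.na(interaction_variable(other_only, cfg)$iv))
})

test_that("distance_profile bins half-open intervals and reports both directions", {
  cfg <- proximity_config()
  region <- make_region(tam = rbind(c(0, 0)),
                        cd8 = rbind(c(0, 3), c(0, 7), c(0, 12)))
  prof <- distance_profile(region, cfg)
  expect_equal(prof$bin_edges, seq(0, 100, 5))
  expect_equal(prof$per_bin_counts[1:3], c(1L, 1L, 1L))
  expect_equal(sum(prof$per_bin_counts), 3L)
  expect_equal(prof$cumulative_proportions[1:3], c(1, 2, 3) / 3)
  expect_true(all(diff(prof$cumulative_proportions) >= 0))
  # TAM -> nearest CD8 direction for the median
  expect_equal(prof$median_nn_distance, 3)
  # exactly 5.0 falls in [5, 10)
  edge <- make_region(tam = rbind(c(0, 0)), cd8 = rbind(c(0, 5)))
  expect_equal(distance_profile(edge, cfg)$per_bin_counts[1:2], c(0L, 1L))
  # zero TAMs: all counts zero, median undefined
  no_tam <- make_region(cd8 = rbind(c(0, 3)))
  prof0 <- distance_profile(no_tam, cfg)
  expect_equal(sum(prof0$per_bin_counts), 0L)
  expect_true(is.na(prof0$median_nn_distance))
})

test_that("attraction left-shifts the cumulative proximity curve", {
  set.seed(77)
  cfg <- simulation_config(attraction_pi = 1, sigma = 8)
  cfg0 <- simulation_config(attraction_pi = 0)
  pcfg <- proximity_config()
  cum_at <- function(cfg, n = 30) {
    rowMeans(vapply(seq_len(n), function(i) {
      r <- simulate_region(cfg, "P", paste0("R", i))
      distance_profile(r, pcfg)$cumulative_proportions
    }, numeric(20)))
  }
  attracted <- cum_at(cfg); csr <- cum_at(cfg0)
  edges_50 <- 1:10  # bins up to 50 um
  expect_true(all(attracted[edges_50] > csr[edges_50]))
})

test_that("patient aggregation pools counts or averages region scores", {
  cfg <- proximity_config()
  # region A: counts (2 within, denominator 6); region B: (4, 14)
  a <- make_region(tam = rbind(c(0, 0), c(100, 0)),
                   cd8 = rbind(c(0, 20), c(0, 24), c(60, 0), c(100, 30)),
                   region_id = "RA")
  b <- make_region(
    tam = cbind(seq(0, 500, length.out = 6), rep(0, 6)),
    cd8 = rbind(c(0, 10), c(100, 10), c(200, 10), c(300, 10),
                c(0, 200), c(100, 200), c(200, 200), c(300, 200)),
    region_id = "RB")
  stopifnot(interaction_variable(b, cfg)$n_cd8_within == 4)
  pooled <- aggregate_patient_iv(list(a, b), cfg, method = "pooled")
  expect_equal(pooled$iv, 100 * 6 / 20)
  m <- aggregate_patient_iv(list(a, b), cfg, method = "mean")
  expect_equal(m$iv, (100 * 2 / 6 + 100 * 4 / 14) / 2)
  # single region: both methods equal the region score
  expect_equal(aggregate_patient_iv(list(a), cfg, "pooled")$iv,
               interaction_variable(a, cfg)$iv)
  expect_equal(aggregate_patient_iv(list(a), cfg, "mean")$iv,
               interaction_variable(a, cfg)$iv)
  # undefined regions: zeros in pooled sums, excluded from the mean
  empty <- make_region(other = rbind(c(1, 1)), region_id = "RC")
  expect_equal(aggregate_patient_iv(list(a, empty), cfg, "pooled")$iv,
               100 * 2 / 6)
  expect_equal(aggregate_patient_iv(list(a, empty), cfg, "mean")$iv,
               100 * 2 / 6)
  expect_error(aggregate_patient_iv(list(), cfg), "empty")
  b_other <- b; b_other$patient_id <- "P9"
  expect_error(aggregate_patient_iv(list(a, b_other), cfg), "multiple")
})

test_that("iv is monotone in radius with the correct large-radius limit", {
  set.seed(202)
  radii <- c(5, 15, 25, 40, 60)
  for (i in 1:10) {
    region <- random_region(sample(1:30, 1), sample(1:60, 1), 10)
    ivs <- vapply(radii, function(r) {
      interaction_variable(region, proximity_config(radius = r,
                                                    max_distance = r))$iv
    }, numeric(1))
    expect_true(all(diff(ivs) >= 0))
    res <- interaction_variable(region,
                                proximity_config(radius = 1e6,
                                                 max_distance = 1e6))
    expect_equal(res$iv, 100 * res$n_cd8 / (res$n_cd8 + res$n_tam))
  }
})

test_that("metrics are invariant to rigid motions and decoupled from density", {
  set.seed(303)
  region <- random_region(15, 40, 30, width = 300, height = 300)
  cfg <- proximity_config()
  base <- interaction_variable(region, cfg)
  base_d <- nearest_neighbor_distances(region, "CD8_T", "PDL1_TAM")

  theta <- 0.7
  rot <- region
  x <- region$cells$x; y <- region$cells$y
  rot$cells$x <- x * cos(theta) - y * sin(theta) + 800
  rot$cells$y <- x * sin(theta) + y * cos(theta) + 200
  rot$width <- 2000; rot$height <- 2000
  rot <- region_cell_map(rot$region_id, rot$patient_id, 2000, 2000, rot$cells)
  moved <- interaction_variable(rot, cfg)
  expect_equal(moved$n_cd8_within, base$n_cd8_within)
  expect_equal(moved$iv, base$iv)
  expect_equal(nearest_neighbor_distances(rot, "CD8_T", "PDL1_TAM"), base_d,
               tolerance = 1e-9)

  # doubling OTHER density changes nothing
  extra <- region
  more <- tibble::tibble(cell_id = paste0("x", 1:30),
                         x = runif(30, 0, 300), y = runif(30, 0, 300),
                         CD8 = FALSE, CD68 = FALSE, CD163 = FALSE,
                         PDL1 = FALSE, GZMB = FALSE, TIM3 = FALSE,
                         phenotype = "OTHER")
  extra$cells <- rbind(extra$cells, more)
  expect_equal(interaction_variable(extra, cfg)$iv, base$iv)

  # duplicating every CD8 and TAM in place leaves iv unchanged
  dup <- region
  keep <- region$cells$phenotype %in% c("CD8_T", "PDL1_TAM")
  clones <- region$cells[keep, ]
  clones$cell_id <- paste0(clones$cell_id, "_dup")
  dup$cells <- rbind(dup$cells, clones)
  expect_equal(interaction_variable(dup, cfg)$iv, base$iv)
})

test_that("radius sensitivity reports Spearman agreement against the reference", {
  # degenerate cohort: every CD8 coincides with a TAM, so iv is identical at
  # all radii while varying across units
  regions <- lapply(1:5, function(i) {
    pts <- cbind(runif(i + 1, 0, 10), runif(i + 1, 0, 10))
    make_region(tam = pts, cd8 = pts[seq_len(i), , drop = FALSE],
                region_id = paste0("R", i))
  })
  res <- radius_sensitivity(regions, proximity_config())
  expect_equal(res$rho$rho, rep(1, 4), tolerance = 1e-12)
  expect_identical(res$rho$rho[res$rho$radius == 25], 1)
  expect_equal(res$rho$radius, c(25, 15, 30, 50))

  # constant iv column -> undefined correlation, flagged
  const <- lapply(1:4, function(i)
    make_region(tam = rbind(c(0, 0)), cd8 = rbind(c(0, 1)),
                region_id = paste0("C", i)))
  res_const <- radius_sensitivity(const, proximity_config())
  expect_true(all(res_const$rho$constant))
  expect_true(all(is.na(res_const$rho$rho)))

  # fewer than 3 defined units
  few <- lapply(1:2, function(i)
    make_region(tam = rbind(c(0, 0)), cd8 = rbind(c(0, 1)),
                region_id = paste0("F", i)))
  expect_error(radius_sensitivity(few, proximity_config()),
               "insufficient")
})
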
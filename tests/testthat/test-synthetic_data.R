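test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(attraction_pi = 1.2), "attraction_pi")
  expect_error(simulation_config(sigma = 0))
  expect_error(simulation_config(baseline_hazard = 0))
  expect_error(simulation_config(censor_max = -1))
})

test_that("cohorts are reproducible under a seed and distinct across seeds", {
  cfg <- simulation_config(seed = 42, lambda_other = 5e-4)
  a <- simulate_cohort(cfg, 3, c(0, 0.5, 1))
  b <- simulate_cohort(cfg, 3, c(0, 0.5, 1))
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 43
  c <- simulate_cohort(cfg2, 3, c(0, 0.5, 1))
  same <- mapply(function(r1, r2) {
    nrow(r1$cells) == nrow(r2$cells) && all(r1$cells$x == r2$cells$x)
  }, a$regions, c$regions)
  expect_false(any(same))
})

test_that("cohort shape: patients x regions_per_patient", {
  cfg <- simulation_config(seed = 7, regions_per_patient = 3,
                           lambda_other = 1e-4)
  cohort <- simulate_cohort(cfg, 23, runif(23))
  expect_length(cohort$regions, 69)
  expect_equal(nrow(cohort$patients), 23)
  expect_error(simulate_cohort(cfg, 0, numeric(0)), "positive")
  expect_error(simulate_cohort(cfg, 3, c(0.5, 0.5)), "length")
})

test_that("without attraction, CD8 cells form a homogeneous Poisson pattern", {
  set.seed(9)
  cfg <- simulation_config(attraction_pi = 0, width = 200, height = 200,
                           lambda_other = 0)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    r <- simulate_region(cfg, "P", paste0("R", i))
    sum(r$cells$phenotype == "CD8_T")
  }, numeric(1))
  expected <- cfg$lambda_cd8 * cfg$width * cfg$height
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("attraction pulls CD8 cells toward TAMs without changing counts", {
  set.seed(10)
  # lambda_tam * area = 20 at a 316 x 316 um region
  area_side <- sqrt(20 / 2e-4)
  cfg1 <- simulation_config(attraction_pi = 1, sigma = 5, width = area_side,
                            height = area_side, lambda_other = 0)
  cfg0 <- cfg1; cfg0$attraction_pi <- 0
  med_nn <- function(cfg, n = 120) {
    vapply(seq_len(n), function(i) {
      r <- simulate_region(cfg, "P", "R")
      median_nn_distance(nearest_neighbor_distances(r, "PDL1_TAM", "CD8_T"))
    }, numeric(1))
  }
  m1 <- med_nn(cfg1); m0 <- med_nn(cfg0)
  expect_lt(median(m1, na.rm = TRUE), 0.6 * median(m0, na.rm = TRUE))
})

test_that("offspring fall back to uniform when no TAM parent exists", {
  set.seed(11)
  cfg <- simulation_config(lambda_tam = 0, attraction_pi = 1,
                           lambda_other = 0)
  r <- simulate_region(cfg, "P", "R")
  log <- attr(r, "sim_log")
  expect_gt(log$fallback_uniform, 0)
  expect_equal(sum(r$cells$phenotype == "PDL1_TAM"), 0)
  expect_true(all(r$cells$x >= 0 & r$cells$x <= cfg$width))
})

test_that("simulated regions carry flags consistent with their phenotypes", {
  set.seed(12)
  cfg <- simulation_config(attraction_pi = 0.7)
  r <- simulate_region(cfg, "P", "R")
  relabeled <- assign_phenotypes(r)
  expect_identical(relabeled$cells$phenotype, r$cells$phenotype)
  # and they survive the io layer for several seeds
  for (s in 1:3) {
    set.seed(s)
    r <- simulate_region(cfg, "P", "R")
    out <- withr::local_tempfile(fileext = ".csv")
    write_cell_table(list(R = r), out)
    back <- read_cell_table(out, bounds = data.frame(
      region_id = "R", width = cfg$width, height = cfg$height))
    expect_identical(back$R$cells, r$cells)
  }
})

test_that("expected interaction variable is monotone in attraction", {
  set.seed(13)
  cfg <- simulation_config(lambda_other = 0)
  grid <- c(0, 0.5, 1)
  mean_iv <- vapply(grid, function(pi) {
    cfg$attraction_pi <- pi
    mean(vapply(1:40, function(i) {
      interaction_variable(simulate_region(cfg, "P", "R"))$iv
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_iv) > 0))
})

test_that("survival generator obeys the exponential hazard model", {
  cfg <- simulation_config(beta_iv = -0.15, baseline_hazard = 0.02,
                           censor_max = 1095)
  expect_error(simulate_survival(c(1, NA), cfg), "finite")

  # beta < 0: higher scores survive stochastically longer
  set.seed(14)
  iv <- rep(c(5, 45), each = 100)
  medians <- vapply(1:100, function(i) {
    s <- simulate_survival(iv, cfg)
    c(median(s$time[1:100]), median(s$time[101:200]))
  }, numeric(2))
  expect_true(mean(medians[2, ] > medians[1, ]) > 0.95)

  # censor_max -> large: event fraction -> 1
  cfg_far <- cfg; cfg_far$censor_max <- 1e9
  set.seed(15)
  s <- simulate_survival(rep(10, 500), cfg_far)
  expect_gt(mean(s$event), 0.99)

  # beta = 0: the score carries no signal; log-rank on dichotomized halves
  # rejects at roughly the nominal rate
  cfg0 <- cfg; cfg0$beta_iv <- 0
  set.seed(16)
  p <- vapply(1:100, function(i) {
    iv <- runif(60, 0, 50)
    s <- simulate_survival(iv, cfg0)
    logrank_test(dichotomize_at_median(iv), s)$p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.0)  # sanity: p-values vary
  expect_lt(mean(p < 0.05), 0.15) # close to the nominal 5%
})

test_that("functional markers track the region interaction variable", {
  set.seed(17)
  cfg <- simulation_config(marker_slope = 0.04, marker_intercept = -1.5,
                           lambda_other = 0)
  make_cd8_region <- function(i)
    random_region(5, 60, 0, region_id = paste0("R", i))
  # positive slope: positive rank correlation over a 40-region cohort
  ivs <- runif(40, 0, 80)
  frac <- vapply(seq_along(ivs), function(i) {
    r <- simulate_functional_markers(make_cd8_region(i), ivs[i], cfg)
    cd8 <- r$cells$phenotype == "CD8_T"
    mean(r$cells$GZMB[cd8])
  }, numeric(1))
  expect_gt(suppressWarnings(cor(ivs, frac, method = "spearman")), 0.5)

  # zero slope: fractions do not track iv
  cfg0 <- cfg; cfg0$marker_slope <- 0
  frac0 <- vapply(seq_along(ivs), function(i) {
    r <- simulate_functional_markers(make_cd8_region(i), ivs[i], cfg0)
    cd8 <- r$cells$phenotype == "CD8_T"
    mean(r$cells$GZMB[cd8])
  }, numeric(1))
  expect_lt(abs(suppressWarnings(cor(ivs, frac0, method = "spearman"))), 0.4)

  # region without CD8 cells is unchanged
  tam_only <- make_region(tam = rbind(c(1, 1)))
  expect_identical(simulate_functional_markers(tam_only, 50, cfg)$cells,
                   tam_only$cells)
  expect_error(simulate_functional_markers(tam_only, 150, cfg), "0, 100")
  # non-CD8 cells never gain functional markers
  r <- simulate_functional_markers(make_cd8_region(99), 80, cfg)
  non_cd8 <- r$cells$phenotype != "CD8_T"
  expect_false(any(r$cells$GZMB[non_cd8] | r$cells$TIM3[non_cd8]))
})
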
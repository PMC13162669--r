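#' Simulation configuration for synthetic biopsy cohorts
#'
#' Defines the generative model used throughout the test bench: homogeneous
#' Poisson numbers of PD-L1(+) TAMs, CD8 T cells and other cells in a
#' rectangular region, with a parent-offspring (Thomas-like) attraction that
#' moves a fraction `attraction_pi` of the CD8 cells next to a randomly chosen
#' TAM parent (isotropic Gaussian displacement, scale `sigma`). Because
#' attraction only relocates CD8 cells, marginal cell counts are unchanged:
#' proximity, not abundance, carries the signal. Progression-free survival is
#' exponential with log-hazard linear in the measured interaction variable,
#' with independent uniform censoring.
#'
#' Defaults describe a plausible biopsy-core field: a 500 x 500 um region with
#' about 50 PD-L1(+) TAMs, 75 CD8 T cells and 500 other cells per region
#' (densities 2e-4, 3e-4 and 2e-3 cells/um^2), sigma = 10 um (about one cell
#' diameter), three cores per patient, beta_iv = -0.15 per interaction-variable
#' unit and censoring uniform over 3 years. The baseline hazard (0.5/day at
#' interaction score 0) is calibrated so that a cohort with typical scores
#' (around 35 under a uniform attraction mix) progresses in roughly two thirds
#' of patients inside the censoring window, the event fraction seen in
#' advanced-HCC combination-therapy cohorts of this size.
#'
#' @param width,height Region extent, micrometres.
#' @param lambda_tam,lambda_cd8,lambda_other Intensities (cells/um^2).
#' @param attraction_pi Probability in `[0, 1]` that a CD8 cell is placed as
#'   offspring of a random TAM.
#' @param sigma Gaussian displacement scale of offspring, micrometres.
#' @param seed Integer seed for cohort-level reproducibility (`NULL` = use the
#'   session RNG stream).
#' @param regions_per_patient Biopsy cores imaged per patient.
#' @param beta_iv Log-hazard change per interaction-variable unit.
#' @param baseline_hazard Event rate (events/day) at interaction variable 0.
#' @param censor_max Upper bound of the uniform censoring time, days.
#' @param marker_intercept,marker_slope Logistic model for GZMB/TIM3
#'   positivity probability of CD8 cells as a function of the region
#'   interaction variable.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(width = 500, height = 500,
                              lambda_tam = 2e-4, lambda_cd8 = 3e-4,
                              lambda_other = 2e-3,
                              attraction_pi = 0.5, sigma = 10,
                              seed = NULL, regions_per_patient = 3,
                              beta_iv = -0.15, baseline_hazard = 0.5,
                              censor_max = 1095,
                              marker_intercept = -1.5, marker_slope = 0.04) {
  stopifnot(width > 0, height > 0, sigma > 0,
            lambda_tam >= 0, lambda_cd8 >= 0, lambda_other >= 0,
            baseline_hazard > 0, censor_max > 0, regions_per_patient >= 1)
  if (attraction_pi < 0 || attraction_pi > 1)
    stop("attraction_pi must lie in [0, 1]", call. = FALSE)
  structure(list(width = width, height = height, lambda_tam = lambda_tam,
                 lambda_cd8 = lambda_cd8, lambda_other = lambda_other,
                 attraction_pi = attraction_pi, sigma = sigma, seed = seed,
                 regions_per_patient = regions_per_patient, beta_iv = beta_iv,
                 baseline_hazard = baseline_hazard, censor_max = censor_max,
                 marker_intercept = marker_intercept,
                 marker_slope = marker_slope),
            class = "simulation_config")
}

# Draw offspring positions around uniformly chosen TAM parents; positions
# falling outside the region are resampled (new displacement, same parent) up
# to `max_attempts` rounds, then clamped to the nearest boundary point.
place_offspring <- function(n, parent_x, parent_y, sigma, width, height,
                            max_attempts = 100) {
  parent <- sample.int(length(parent_x), n, replace = TRUE)
  x <- parent_x[parent] + rnorm(n, 0, sigma)
  y <- parent_y[parent] + rnorm(n, 0, sigma)
  clamped <- 0L
  for (attempt in seq_len(max_attempts)) {
    out <- which(x < 0 | x > width | y < 0 | y > height)
    if (!length(out)) break
    x[out] <- parent_x[parent[out]] + rnorm(length(out), 0, sigma)
    y[out] <- parent_y[parent[out]] + rnorm(length(out), 0, sigma)
  }
  out <- which(x < 0 | x > width | y < 0 | y > height)
  if (length(out)) {
    clamped <- length(out)
    x[out] <- pmin(pmax(x[out], 0), width)
    y[out] <- pmin(pmax(y[out], 0), height)
  }
  list(x = x, y = y, clamped = clamped)
}

#' Simulate one imaged region
#'
#' TAM and OTHER cells are placed uniformly (binomial point process given the
#' Poisson counts); each CD8 cell is, independently with probability
#' `attraction_pi`, an offspring of a uniformly chosen TAM (Gaussian
#' displacement of scale `sigma`, resampled until inside the region, at most
#' 100 rounds, then clamped to the boundary), otherwise uniform. Marker flags
#' are drawn consistently with each cell's phenotype: PD-L1(+) TAMs carry PDL1
#' plus CD68 and/or CD163; CD8 T cells carry CD8; a fraction of OTHER cells
#' carries macrophage markers without PDL1 (PD-L1-negative macrophages).
#' GZMB/TIM3 start negative (see [simulate_functional_markers()]).
#'
#' Draws from the session RNG stream: seed the stream (or use
#' [simulate_cohort()], which seeds from `config$seed`) for reproducibility.
#'
#' @param config A [simulation_config()].
#' @param patient_id,region_id Identifiers for the generated region.
#' @return A [region_cell_map()] with phenotypes assigned. Attribute
#'   `sim_log` reports offspring fallback-to-uniform and boundary-clamp
#'   counts.
#' @export
simulate_region <- function(config, patient_id, region_id) {
  stopifnot(inherits(config, "simulation_config"))
  area <- config$width * config$height
  n_tam <- rpois(1, config$lambda_tam * area)
  n_cd8 <- rpois(1, config$lambda_cd8 * area)
  n_other <- rpois(1, config$lambda_other * area)

  tam_x <- runif(n_tam, 0, config$width)
  tam_y <- runif(n_tam, 0, config$height)

  fallback <- 0L; clamped <- 0L
  is_offspring <- runif(n_cd8) < config$attraction_pi
  if (any(is_offspring) && n_tam == 0) {
    fallback <- sum(is_offspring)
    is_offspring[] <- FALSE
  }
  cd8_x <- runif(n_cd8, 0, config$width)
  cd8_y <- runif(n_cd8, 0, config$height)
  if (any(is_offspring)) {
    off <- place_offspring(sum(is_offspring), tam_x, tam_y, config$sigma,
                           config$width, config$height)
    cd8_x[is_offspring] <- off$x
    cd8_y[is_offspring] <- off$y
    clamped <- off$clamped
  }

  other_x <- runif(n_other, 0, config$width)
  other_y <- runif(n_other, 0, config$height)

  n <- n_tam + n_cd8 + n_other
  ph <- rep(PHENOTYPES, c(n_tam, n_cd8, n_other))
  cells <- tibble::tibble(
    cell_id = paste0(region_id, "_c", seq_len(n)),
    x = c(tam_x, cd8_x, other_x), y = c(tam_y, cd8_y, other_y),
    CD8 = ph == "CD8_T",
    CD68 = FALSE, CD163 = FALSE, PDL1 = ph == "PDL1_TAM",
    GZMB = FALSE, TIM3 = FALSE, phenotype = ph)
  if (n_tam > 0) {
    i <- seq_len(n_tam)
    cells$CD68[i] <- runif(n_tam) < 0.7
    cells$CD163[i] <- runif(n_tam) < 0.6
    none <- i[!cells$CD68[i] & !cells$CD163[i]]
    cells$CD68[none] <- TRUE
  }
  if (n_other > 0) {
    # PD-L1-negative macrophages among the OTHER compartment
    i <- n_tam + n_cd8 + seq_len(n_other)
    mac <- i[runif(n_other) < 0.3]
    cells$CD68[mac] <- runif(length(mac)) < 0.7
    cells$CD163[mac] <- runif(length(mac)) < 0.6
  }

  region <- region_cell_map(region_id, patient_id, config$width,
                            config$height, cells)
  attr(region, "sim_log") <- list(fallback_uniform = fallback,
                                  clamped = clamped)
  region
}

#' Simulate a multi-region cohort
#'
#' Each patient receives `config$regions_per_patient` regions generated at
#' that patient's attraction probability; marginal intensities are shared
#' across the cohort. Reproducible: `config$seed` (when non-`NULL`) seeds the
#' RNG stream before generation.
#'
#' @param config A [simulation_config()].
#' @param n_patients Number of patients (positive).
#' @param attraction_values Per-patient attraction probabilities
#'   (length `n_patients`, each in `[0, 1]`).
#' @param arm Treatment-arm label stored in the patient skeletons.
#' @return A list with `regions` (named list of [region_cell_map()]) and
#'   `patients` (tibble: `patient_id`, `arm`, `attraction_pi`).
#' @export
simulate_cohort <- function(config, n_patients, attraction_values,
                            arm = "AtezoBev") {
  stopifnot(inherits(config, "simulation_config"))
  if (n_patients <= 0) stop("n_patients must be positive", call. = FALSE)
  if (length(attraction_values) != n_patients)
    stop("attraction_values must have length n_patients", call. = FALSE)
  if (any(attraction_values < 0 | attraction_values > 1))
    stop("attraction_values must lie in [0, 1]", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  patient_ids <- sprintf("P%03d", seq_len(n_patients))
  regions <- list()
  for (p in seq_len(n_patients)) {
    cfg_p <- config
    cfg_p$attraction_pi <- attraction_values[p]
    for (r in seq_len(config$regions_per_patient)) {
      rid <- sprintf("%s_R%d", patient_ids[p], r)
      regions[[rid]] <- simulate_region(cfg_p, patient_ids[p], rid)
    }
  }
  patients <- tibble::tibble(patient_id = patient_ids, arm = arm,
                             attraction_pi = attraction_values)
  list(regions = regions, patients = patients)
}

#' Simulate progression-free survival from interaction-variable scores
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta_iv * iv)`; censoring times are uniform on
#' `(0, censor_max)`; the observed time is the minimum and the event flag
#' indicates the event came first. With `beta_iv < 0`, higher interaction
#' scores mean stochastically longer survival (protective marker).
#'
#' @param iv_values Per-patient interaction-variable scores (finite).
#' @param config A [simulation_config()] supplying `beta_iv`,
#'   `baseline_hazard` and `censor_max`.
#' @return A tibble with columns `time` (days) and `event` (1 = observed).
#' @export
simulate_survival <- function(iv_values, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!all(is.finite(iv_values)))
    stop("iv_values must all be finite", call. = FALSE)
  n <- length(iv_values)
  rate <- config$baseline_hazard * exp(config$beta_iv * iv_values)
  t_event <- rexp(n, rate = rate)
  t_cens <- runif(n, 0, config$censor_max)
  tibble::tibble(time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
}

#' Add GZMB/TIM3 positivity to the CD8 cells of a region
#'
#' Each CD8 T cell independently gains GZMB, and independently TIM3,
#' positivity with probability
#' `plogis(marker_intercept + marker_slope * region_iv)`; non-CD8 cells are
#' unchanged. With a positive slope, regions with stronger TAM-CD8 interaction
#' carry larger effector (GZMB) and exhaustion (TIM3) fractions among their
#' CD8 cells.
#'
#' @param region A [region_cell_map()] with phenotypes assigned.
#' @param region_iv The region's interaction variable, in `[0, 100]`.
#' @param config A [simulation_config()].
#' @return The region with updated GZMB/TIM3 flags.
#' @export
simulate_functional_markers <- function(region, region_iv, config) {
  stopifnot(inherits(region, "region_cell_map"),
            inherits(config, "simulation_config"))
  if (!is.finite(region_iv) || region_iv < 0 || region_iv > 100)
    stop("region_iv must lie in [0, 100]", call. = FALSE)
  if (anyNA(region$cells$phenotype))
    stop("phenotypes must be assigned first", call. = FALSE)
  cd8 <- which(region$cells$phenotype == "CD8_T")
  if (!length(cd8)) return(region)
  p <- plogis(config$marker_intercept + config$marker_slope * region_iv)
  region$cells$GZMB[cd8] <- runif(length(cd8)) < p
  region$cells$TIM3[cd8] <- runif(length(cd8)) < p
  region
}

#' Build a full synthetic patient table
#'
#' Completes the cohort skeletons from [simulate_cohort()] into the standard
#' clinical table: covariates drawn from distributions shaped like an advanced
#' hepatocellular carcinoma cohort (age, sex, etiology, AFP, DCP, tumor
#' burden, vascular invasion, albumin/bilirubin), PFS generated from the
#' measured interaction variable via [simulate_survival()], OS as a stretched
#' version of the same hazard, and % tumor-size change at first assessment
#' negatively associated with the interaction variable. All covariates other
#' than those derived from `iv_values` are independent noise.
#'
#' @param patients Patient skeleton tibble (`patient_id`, `arm`, ...).
#' @param iv_values Measured per-patient interaction variables (same order).
#' @param config A [simulation_config()].
#' @return A tibble with the standard patient-table columns plus
#'   `attraction_pi` and `iv` for ground-truth bookkeeping.
#' @export
simulate_patient_table <- function(patients, iv_values, config) {
  n <- nrow(patients)
  stopifnot(length(iv_values) == n)
  pfs <- simulate_survival(iv_values, config)
  os_cfg <- config
  os_cfg$baseline_hazard <- config$baseline_hazard / 2
  os <- simulate_survival(iv_values, os_cfg)
  os$time <- pmax(os$time, pfs$time)  # OS cannot precede progression
  size_change <- round(-0.8 * (iv_values - mean(iv_values)) + rnorm(n, 5, 20),
                       1)
  out <- tibble::tibble(
    patient_id = patients$patient_id,
    arm = patients$arm,
    age = sample(50:85, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2)),
    etiology = sample(c("HBV", "HCV", "NBNC"), n, replace = TRUE,
                      prob = c(0.15, 0.25, 0.6)),
    afp = round(rlnorm(n, log(20), 1.5), 1),
    dcp = round(rlnorm(n, log(200), 1.5), 0),
    max_tumor_size_cm = round(rlnorm(n, log(4), 0.5), 1),
    tumor_number = sample(1:5, n, replace = TRUE),
    vascular_invasion = rbinom(n, 1, 0.3),
    extrahepatic_metastasis = rbinom(n, 1, 0.25),
    bclc = sample(c("B", "C"), n, replace = TRUE),
    child_pugh = sample(5:7, n, replace = TRUE),
    albumin_g_dl = round(runif(n, 2.8, 4.5), 1),
    bilirubin_mg_dl = round(runif(n, 0.4, 2.0), 2),
    size_change_pct = pmax(pmin(size_change, 100), -100),
    pfs_days = pmax(pfs$time, 1), pfs_event = pfs$event,
    os_days = pmax(os$time, 1), os_event = os$event)
  out$attraction_pi <- patients$attraction_pi
  out$iv <- iv_values
  out
}
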
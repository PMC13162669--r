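#' Proximity analysis configuration
#'
#' @param radius Reference interaction radius in micrometres (default 25 um,
#'   about one to two cell diameters, capturing direct contact and short-range
#'   paracrine interaction).
#' @param sensitivity_radii Alternative radii for the sensitivity analysis
#'   (default 15, 30, 50 um).
#' @param bin_width Width of the distance-profile bins (default 5 um).
#' @param max_distance Upper edge of the distance profile (default 100 um).
#' @param boundary_inclusive If `TRUE` (default), a CD8 cell at exactly the
#'   radius counts as within it ("within r" read as `<=`).
#' @return A list of class `proximity_config`.
#' @export
proximity_config <- function(radius = 25, sensitivity_radii = c(15, 30, 50),
                             bin_width = 5, max_distance = 100,
                             boundary_inclusive = TRUE) {
  stopifnot(radius > 0, bin_width > 0, max_distance >= radius,
            all(sensitivity_radii > 0),
            !anyDuplicated(sensitivity_radii))
  structure(list(radius = radius, sensitivity_radii = sensitivity_radii,
                 bin_width = bin_width, max_distance = max_distance,
                 boundary_inclusive = boundary_inclusive),
            class = "proximity_config")
}

phenotype_xy <- function(region, phenotype) {
  if (!phenotype %in% PHENOTYPES)
    stop("unknown phenotype label '", phenotype, "'", call. = FALSE)
  if (anyNA(region$cells$phenotype))
    stop("phenotypes must be assigned before spatial analysis", call. = FALSE)
  keep <- region$cells$phenotype == phenotype
  list(x = region$cells$x[keep], y = region$cells$y[keep], n = sum(keep))
}

# squared distance from each source cell to its nearest target cell
# (Inf when no target exists)
nn_sqdist <- function(region, from_phenotype, to_phenotype) {
  src <- phenotype_xy(region, from_phenotype)
  tgt <- phenotype_xy(region, to_phenotype)
  nn_sqdist_grid(src$x, src$y, tgt$x, tgt$y)
}

#' Nearest-neighbor distances between two phenotypes
#'
#' For every cell of `from_phenotype`, the Euclidean distance (micrometres) to
#' the closest cell of `to_phenotype` within the same region. Directional:
#' TAM-to-nearest-CD8 and CD8-to-nearest-TAM are different quantities. The
#' neighbor search is a grid-bucketed accelerated scan in compiled code.
#'
#' @param region A [region_cell_map()] with phenotypes assigned.
#' @param from_phenotype,to_phenotype Phenotype labels (`"PDL1_TAM"`,
#'   `"CD8_T"`, `"OTHER"`).
#' @return Numeric vector, one entry per source cell; `NA` when the region
#'   holds no target cell.
#' @export
nearest_neighbor_distances <- function(region, from_phenotype, to_phenotype) {
  d2 <- nn_sqdist(region, from_phenotype, to_phenotype)
  d <- sqrt(d2)
  d[!is.finite(d)] <- NA_real_
  d
}

#' Median nearest-neighbor distance
#'
#' Median of the defined entries of a nearest-neighbor distance list
#' (undefined entries excluded; even counts use the midpoint convention).
#'
#' @param distances Numeric vector, possibly with `NA` entries.
#' @return The median in micrometres, or `NA` when no entry is defined.
#' @export
median_nn_distance <- function(distances) {
  d <- distances[!is.na(distances)]
  if (!length(d)) return(NA_real_)
  median(d)
}

#' Count CD8 T cells within a radius of at least one PD-L1(+) TAM
#'
#' Each CD8 cell is counted at most once, however many TAMs are near it.
#' Comparisons use squared distances, so the boundary decision is exact.
#'
#' @param region A [region_cell_map()] with phenotypes assigned.
#' @param radius Radius in micrometres (positive).
#' @param boundary_inclusive If `TRUE`, distance equal to `radius` counts as
#'   within (`<=`); otherwise strict (`<`).
#' @return Integer count.
#' @export
count_cd8_within <- function(region, radius, boundary_inclusive = TRUE) {
  stopifnot(radius > 0)
  d2 <- nn_sqdist(region, "CD8_T", "PDL1_TAM")
  r2 <- radius * radius
  if (boundary_inclusive) sum(d2 <= r2) else sum(d2 < r2)
}

#' The normalized TAM-CD8 interaction variable of one region
#'
#' Counts the CD8 T cells lying within `config$radius` of at least one
#' PD-L1(+) TAM, and normalizes:
#' `iv = 100 * n_cd8_within / (n_cd8 + n_tam)`.
#' The normalization makes the score reflect the relative frequency of
#' interacting cells rather than the absolute abundance of either population.
#' When the region holds TAMs or CD8 cells but not both, the score is a
#' defined 0; only a region empty of both phenotypes yields `NA` (propagated
#' as missing, never as 0).
#'
#' @param region A [region_cell_map()] with phenotypes assigned.
#' @param config A [proximity_config()].
#' @return One-row tibble: `region_id`, `patient_id`, `n_cd8`, `n_tam`,
#'   `n_cd8_within`, `radius`, `iv`.
#' @export
interaction_variable <- function(region, config = proximity_config()) {
  stopifnot(inherits(config, "proximity_config"))
  n_cd8 <- phenotype_xy(region, "CD8_T")$n
  n_tam <- phenotype_xy(region, "PDL1_TAM")$n
  n_within <- if (n_cd8 > 0 && n_tam > 0)
    count_cd8_within(region, config$radius, config$boundary_inclusive)
  else 0L
  denom <- n_cd8 + n_tam
  iv <- if (denom > 0) 100 * n_within / denom else NA_real_
  tibble::tibble(region_id = region$region_id, patient_id = region$patient_id,
                 n_cd8 = n_cd8, n_tam = n_tam,
                 n_cd8_within = as.integer(n_within),
                 radius = config$radius, iv = iv)
}

#' Distance-binned proximity profile of CD8 cells around TAMs
#'
#' Bins each CD8 T cell by its distance to the nearest PD-L1(+) TAM into
#' half-open intervals `[k*bin_width, (k+1)*bin_width)` up to `max_distance`,
#' with running cumulative proportions over the region's total CD8 count, and
#' reports the median TAM-to-nearest-CD8 distance.
#'
#' @param region A [region_cell_map()] with phenotypes assigned.
#' @param config A [proximity_config()].
#' @return A list of class `distance_profile`: `bin_edges` (0, bin_width, ...,
#'   max_distance), `per_bin_counts`, `cumulative_proportions`,
#'   `median_nn_distance` (TAM to nearest CD8; `NA` when undefined).
#' @export
distance_profile <- function(region, config = proximity_config()) {
  stopifnot(inherits(config, "proximity_config"))
  edges <- seq(0, config$max_distance, by = config$bin_width)
  n_bins <- length(edges) - 1
  d_cd8 <- nearest_neighbor_distances(region, "CD8_T", "PDL1_TAM")
  n_cd8 <- length(d_cd8)
  in_range <- !is.na(d_cd8) & d_cd8 < config$max_distance
  counts <- tabulate(floor(d_cd8[in_range] / config$bin_width) + 1L,
                     nbins = n_bins)
  cumulative <- if (n_cd8 > 0) cumsum(counts) / n_cd8 else rep(0, n_bins)
  med <- median_nn_distance(
    nearest_neighbor_distances(region, "PDL1_TAM", "CD8_T"))
  structure(list(bin_edges = edges, per_bin_counts = as.integer(counts),
                 cumulative_proportions = cumulative,
                 median_nn_distance = med),
            class = "distance_profile")
}

#' Aggregate region interaction variables to the patient level
#'
#' `pooled` (default) sums interaction counts and denominators across the
#' patient's cores before normalizing, weighting cores by their cellularity;
#' `mean` averages the defined per-core scores unweighted. Cores with an
#' undefined score contribute zero cells to the pooled sums and are excluded
#' from the mean.
#'
#' @param regions Nonempty list of [region_cell_map()] sharing one
#'   `patient_id`.
#' @param config A [proximity_config()].
#' @param method `"pooled"` or `"mean"`.
#' @return One-row tibble like [interaction_variable()] (with
#'   `region_id = NA`); counts are summed across cores.
#' @export
aggregate_patient_iv <- function(regions, config = proximity_config(),
                                 method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (!length(regions)) stop("empty region list", call. = FALSE)
  pid <- unique(vapply(regions, function(r) r$patient_id, character(1)))
  if (length(pid) != 1)
    stop("regions span multiple patient ids: ",
         paste(pid, collapse = ", "), call. = FALSE)
  per_region <- do.call(rbind, lapply(regions, interaction_variable,
                                      config = config))
  n_cd8 <- sum(per_region$n_cd8); n_tam <- sum(per_region$n_tam)
  n_within <- sum(per_region$n_cd8_within)
  iv <- if (method == "pooled") {
    if (n_cd8 + n_tam > 0) 100 * n_within / (n_cd8 + n_tam) else NA_real_
  } else {
    defined <- per_region$iv[!is.na(per_region$iv)]
    if (length(defined)) mean(defined) else NA_real_
  }
  tibble::tibble(region_id = NA_character_, patient_id = pid,
                 n_cd8 = n_cd8, n_tam = n_tam, n_cd8_within = n_within,
                 radius = config$radius, iv = iv)
}

#' Radius-sensitivity analysis of the interaction variable
#'
#' Recomputes every region's interaction variable at the reference radius and
#' each alternative radius, then reports the Spearman rank correlation
#' (average ranks for ties, two-sided p by the t approximation) of each
#' radius column against the reference. A constant column yields `NA`
#' correlation, flagged in the output.
#'
#' @param regions List of [region_cell_map()] (the analysis units).
#' @param config A [proximity_config()]; radii taken from
#'   `c(radius, sensitivity_radii)`.
#' @return A list of class `radius_sensitivity`: `iv_by_radius` (tibble
#'   `region_id`, `patient_id`, one `iv_<r>` column per radius) and `rho`
#'   (tibble `radius`, `rho`, `p_value`, `constant` flag).
#' @export
radius_sensitivity <- function(regions, config = proximity_config()) {
  stopifnot(inherits(config, "proximity_config"))
  radii <- c(config$radius, config$sensitivity_radii)
  cols <- lapply(radii, function(r) {
    cfg <- config; cfg$radius <- r
    vapply(regions, function(reg) interaction_variable(reg, cfg)$iv,
           numeric(1))
  })
  ref <- cols[[1]]
  if (sum(!is.na(ref)) < 3)
    stop("insufficient data: need at least 3 analysis units with a defined ",
         "interaction variable", call. = FALSE)
  iv_tab <- tibble::tibble(
    region_id = vapply(regions, function(r) r$region_id, character(1)),
    patient_id = vapply(regions, function(r) r$patient_id, character(1)))
  for (i in seq_along(radii)) iv_tab[[paste0("iv_", radii[i])]] <- cols[[i]]

  rho_rows <- lapply(seq_along(radii), function(i) {
    v <- cols[[i]]
    ok <- !is.na(v) & !is.na(ref)
    constant <- sd(v[ok]) == 0 || sd(ref[ok]) == 0
    if (constant) {
      tibble::tibble(radius = radii[i], rho = NA_real_, p_value = NA_real_,
                     constant = TRUE)
    } else {
      ct <- suppressWarnings(
        cor.test(v[ok], ref[ok], method = "spearman", exact = FALSE))
      # self-correlation of the reference column is 1 by definition
      rho <- if (i == 1) 1 else unname(ct$estimate)
      tibble::tibble(radius = radii[i], rho = rho,
                     p_value = ct$p.value, constant = FALSE)
    }
  })
  structure(list(iv_by_radius = iv_tab, rho = do.call(rbind, rho_rows),
                 reference_radius = config$radius),
            class = "radius_sensitivity")
}
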
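#' Construct a region cell map
#'
#' A region cell map holds every segmented cell of one imaged region (one
#' needle-biopsy core field), its rectangular geometry in micrometres, and the
#' patient it belongs to. Coordinates use the image convention: origin at the
#' top-left corner, y increasing downward. Only Euclidean distances are
#' consumed downstream, so the convention is documentation-only.
#'
#' @param region_id Region identifier, unique within a cohort.
#' @param patient_id Patient identifier.
#' @param width,height Region extent in micrometres (positive).
#' @param cells A data frame with one row per cell: `cell_id`, `x`, `y`
#'   (micrometres), logical marker flags `CD8`, `CD68`, `CD163`, `PDL1`,
#'   `GZMB`, `TIM3`, and (optionally) a `phenotype` label in
#'   `c("PDL1_TAM", "CD8_T", "OTHER")` or `NA` when not yet assigned.
#' @return An object of class `region_cell_map`.
#' @export
region_cell_map <- function(region_id, patient_id, width, height, cells) {
  stopifnot(is.numeric(width), is.numeric(height))
  if (width <= 0 || height <= 0)
    stop("region dimensions must be positive", call. = FALSE)
  cells <- tibble::as_tibble(cells)
  if (!"phenotype" %in% names(cells)) cells$phenotype <- NA_character_
  required <- c("cell_id", "x", "y", MARKERS)
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop("cells table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (m in MARKERS) {
    if (!is.logical(cells[[m]]))
      stop("marker flag '", m, "' must be logical", call. = FALSE)
  }
  if (nrow(cells) > 0) {
    bad <- which(cells$x < 0 | cells$x > width | cells$y < 0 |
                   cells$y > height | !is.finite(cells$x) | !is.finite(cells$y))
    if (length(bad))
      stop("region '", region_id, "': ", length(bad),
           " cell(s) outside [0, width] x [0, height] (first at row ",
           bad[1], ")", call. = FALSE)
  }
  structure(
    list(region_id = as.character(region_id),
         patient_id = as.character(patient_id),
         width = as.numeric(width), height = as.numeric(height),
         cells = cells[c("cell_id", "x", "y", MARKERS, "phenotype")]),
    class = "region_cell_map")
}

#' @export
print.region_cell_map <- function(x, ...) {
  cat("<region_cell_map> region", x$region_id, "| patient", x$patient_id,
      sprintf("| %g x %g um | %d cells\n", x$width, x$height, nrow(x$cells)))
  if (any(!is.na(x$cells$phenotype))) {
    tab <- table(factor(x$cells$phenotype, levels = PHENOTYPES))
    cat("  phenotypes:", paste(names(tab), tab, sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Phenotyping rule for composite marker calls
#'
#' Maps the six marker positivity flags to one of three mutually exclusive
#' phenotypes. The default tumor-associated macrophage (TAM) gate is
#' CD68-positive OR CD163-positive (covering pan- and M2-macrophage staining),
#' and a PD-L1(+) TAM additionally requires PDL1. A CD8-positive cell is a
#' CD8 T cell. Cells matching both gates are resolved by `precedence`
#' (default: `PDL1_TAM` wins); everything else is `OTHER`.
#'
#' @param tam Predicate: data frame of logical marker flags -> logical vector
#'   marking PD-L1(+) TAMs.
#' @param cd8 Predicate marking CD8 T cells.
#' @param precedence Character vector ordering `"PDL1_TAM"` and `"CD8_T"`;
#'   the earlier label wins for cells matching both predicates.
#' @return An object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(
    tam = function(flags) (flags$CD68 | flags$CD163) & flags$PDL1,
    cd8 = function(flags) flags$CD8,
    precedence = c("PDL1_TAM", "CD8_T")) {
  if (!setequal(precedence, c("PDL1_TAM", "CD8_T")))
    stop("precedence must order PDL1_TAM and CD8_T", call. = FALSE)
  structure(list(tam = tam, cd8 = cd8, precedence = precedence),
            class = "phenotype_rule")
}

#' Assign phenotypes to every cell of a region
#'
#' Applies a [phenotype_rule()] to the marker flags. Every cell receives
#' exactly one label; the assignment is a pure function of the flags (and so
#' idempotent). Cells matching both the TAM and CD8 gates are resolved by the
#' rule's precedence list rather than dropped; their count is reported via the
#' `n_double_positive` attribute.
#'
#' @param region A [region_cell_map()].
#' @param rule A [phenotype_rule()].
#' @return The region with `cells$phenotype` filled; attributes
#'   `phenotype_counts` (named integer vector) and `n_double_positive`.
#' @export
assign_phenotypes <- function(region, rule = phenotype_rule()) {
  stopifnot(inherits(region, "region_cell_map"))
  flags <- region$cells[MARKERS]
  is_tam <- rule$tam(flags)
  is_cd8 <- rule$cd8(flags)
  if (anyNA(is_tam) || anyNA(is_cd8))
    stop("phenotype predicates returned NA: rule does not cover all flag ",
         "combinations", call. = FALSE)
  ph <- rep("OTHER", nrow(flags))
  masks <- list(PDL1_TAM = is_tam, CD8_T = is_cd8)
  # later assignments overwrite earlier ones, so apply in reverse precedence
  for (label in rev(rule$precedence)) ph[masks[[label]]] <- label
  region$cells$phenotype <- ph
  counts <- table(factor(ph, levels = PHENOTYPES))
  attr(region, "phenotype_counts") <- setNames(as.integer(counts),
                                               names(counts))
  attr(region, "n_double_positive") <- sum(is_tam & is_cd8)
  region
}

truthy_flag <- function(x, column, truthy = c("1", "true", "yes", "t", "y"),
                        falsy = c("0", "false", "no", "f", "n")) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% truthy] <- TRUE
  out[lx %in% falsy] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("column '", column, "': unrecognized flag value '", x[bad],
         "' at data row ", bad, call. = FALSE)
  }
  out
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a cell-segmentation table into region cell maps
#'
#' Reads delimited text in the style of inForm/phenoptr cell-seg exports: one
#' row per cell with columns `patient_id, region_id, cell_id, x_um, y_um` and
#' the six marker flags (`CD8, CD68, CD163, PDL1, GZMB, TIM3`; accepted
#' encodings 0/1, true/false, yes/no, case-insensitive), plus an optional
#' `phenotype` column. Both comma- and tab-delimited files are accepted.
#'
#' The on-disk format carries no region geometry, so bounds come from the
#' `bounds` argument when given; otherwise each region's width and height are
#' inferred as the ceiling of its maximum x and y coordinate.
#'
#' @param path File path.
#' @param delim Field delimiter; `NULL` (default) sniffs `","` vs `"\t"` from
#'   the header line.
#' @param bounds Optional data frame `region_id, width, height` declaring
#'   region geometry; coordinates outside the declared bounds are an error.
#' @return A named list of [region_cell_map()], one per distinct `region_id`
#'   in file order; cells preserve file order.
#' @export
read_cell_table <- function(path, delim = NULL, bounds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing <- setdiff(CELL_TABLE_COLUMNS, names(raw))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  parse_um <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) || anyNA(raw[[col]]))
      stop("column '", col, "': non-numeric coordinate at data row ",
           c(bad, which(is.na(raw[[col]])))[1], call. = FALSE)
    v
  }
  x <- parse_um("x_um"); y <- parse_um("y_um")
  flags <- lapply(MARKERS, function(m) truthy_flag(raw[[m]], m))
  names(flags) <- MARKERS
  phenotype <- if ("phenotype" %in% names(raw)) {
    ph <- raw$phenotype
    bad <- !is.na(ph) & !ph %in% PHENOTYPES
    if (any(bad))
      stop("column 'phenotype': unknown label '", ph[bad][1], "'",
           call. = FALSE)
    ph
  } else rep(NA_character_, nrow(raw))

  cells_all <- tibble::tibble(
    patient_id = raw$patient_id, region_id = raw$region_id,
    cell_id = raw$cell_id, x = x, y = y)
  for (m in MARKERS) cells_all[[m]] <- flags[[m]]
  cells_all$phenotype <- phenotype

  region_ids <- unique(cells_all$region_id)
  out <- lapply(region_ids, function(rid) {
    rows <- cells_all[cells_all$region_id == rid, ]
    pid <- unique(rows$patient_id)
    if (length(pid) != 1)
      stop("region '", rid, "' maps to multiple patient ids", call. = FALSE)
    if (!is.null(bounds)) {
      b <- bounds[bounds$region_id == rid, ]
      if (nrow(b) != 1)
        stop("no bounds declared for region '", rid, "'", call. = FALSE)
      w <- b$width; h <- b$height
    } else {
      w <- max(ceiling(rows$x), 1); h <- max(ceiling(rows$y), 1)
    }
    region_cell_map(rid, pid, w, h,
                    rows[c("cell_id", "x", "y", MARKERS, "phenotype")])
  })
  names(out) <- region_ids
  out
}

#' Write region cell maps to a delimited cell table
#'
#' Inverse of [read_cell_table()]: coordinates are written at full double
#' precision and marker flags as 0/1, so a write/read round trip reproduces
#' the cells exactly. Region geometry is not stored in the table (see
#' [read_cell_table()]'s `bounds` argument).
#'
#' @param regions A list of [region_cell_map()] (may be empty).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(regions, path, delim = ",") {
  rows <- lapply(regions, function(r) {
    stopifnot(inherits(r, "region_cell_map"))
    out <- tibble::tibble(patient_id = rep(r$patient_id, nrow(r$cells)),
                          region_id = rep(r$region_id, nrow(r$cells)))
    cbind(out, r$cells)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    empty <- tibble::tibble(patient_id = character(), region_id = character(),
                            cell_id = character(), x = numeric(),
                            y = numeric())
    for (m in MARKERS) empty[[m]] <- logical()
    empty$phenotype <- character()
    empty
  }
  names(tab)[names(tab) == "x"] <- "x_um"
  names(tab)[names(tab) == "y"] <- "y_um"
  for (m in MARKERS) tab[[m]] <- as.integer(tab[[m]])
  if (all(is.na(tab$phenotype))) tab$phenotype <- NULL
  readr::write_delim(tibble::as_tibble(tab), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}

#' Read a patient clinical table
#'
#' Delimited text with one row per patient: treatment arm, clinical
#' covariates, % tumor-size change at first radiological assessment, and
#' progression-free / overall survival times (days) with event flags.
#'
#' @param path File path.
#' @param delim Delimiter; `NULL` sniffs comma vs tab.
#' @return A tibble with the standard patient columns.
#' @export
read_patient_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- sniff_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing <- setdiff(PATIENT_TABLE_COLUMNS, names(tab))
  if (length(missing))
    stop("patient table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab
}

#' Write a patient clinical table
#'
#' @param patients Data frame with the standard patient columns.
#' @param path Output file path.
#' @param delim Delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path, delim = ",") {
  missing <- setdiff(PATIENT_TABLE_COLUMNS, names(patients))
  if (length(missing))
    stop("patient table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  readr::write_delim(tibble::as_tibble(patients), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}
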
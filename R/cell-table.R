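#' Per-cell segmentation table
#'
#' Typed tibble of per-cell records exported by image-analysis software after
#' segmentation and phenotyping: one row per segmented nucleus with its
#' tissue section, probe combination, phenotype label (possibly `"Other"` for
#' unphenotyped cells), nuclear area in square microns, an optional nuclear
#' radius in microns, and the transcript copy count of a total-RNA marker
#' gene (a TREG such as *AKT3*), which proxies the cell's RNA content.
#'
#' @param df Data frame with columns `section_id`, `phenotype`,
#'   `nuclear_area` and optionally `combination`, `radius`, `treg_copies`.
#' @return A `cell_table` tibble.
#' @export
cell_table <- function(df) {
  df <- as_tibble(df)
  needed <- c("section_id", "phenotype", "nuclear_area")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("cell table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$nuclear_area)) {
    stop("`nuclear_area` must be numeric", call. = FALSE)
  }
  if (any(!is.na(df$nuclear_area) & df$nuclear_area <= 0)) {
    stop("`nuclear_area` must be positive", call. = FALSE)
  }
  if (anyNA(df$phenotype)) {
    stop("`phenotype` must be non-missing for every cell", call. = FALSE)
  }
  df$section_id <- as.character(df$section_id)
  df$phenotype <- as.character(df$phenotype)
  if (!"combination" %in% names(df)) df$combination <- "other"
  bad <- !df$combination %in% c("Star", "Circle")
  df$combination[bad] <- "other"
  if ("radius" %in% names(df)) {
    if (any(!is.na(df$radius) & df$radius <= 0)) {
      stop("`radius` must be positive where present", call. = FALSE)
    }
  }
  if ("treg_copies" %in% names(df)) {
    if (any(!is.na(df$treg_copies) & df$treg_copies < 0)) {
      stop("`treg_copies` must be non-negative", call. = FALSE)
    }
  }
  class(df) <- c("cell_table", class(tibble()))
  df
}

#' Read a segmentation export into a cell table
#'
#' Consumes CSV exports from image-analysis pipelines. Column names vary
#' between export versions, so a name mapping can be supplied, e.g.
#' `c(nuclear_area = "Nucleus Area (µm²)")`.
#'
#' @param csv_path Path to the CSV export.
#' @param col_map Named character vector mapping the canonical names
#'   (`section_id`, `phenotype`, `nuclear_area`, `radius`, `treg_copies`,
#'   `combination`) to columns in the file.
#' @return A validated [cell_table()].
#' @export
read_cell_table <- function(csv_path, col_map = NULL) {
  df <- readr::read_csv(csv_path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df)) {
        stop("mapped column '", src, "' not found in ", csv_path,
             call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  cell_table(df)
}

#' Exclude implausibly large cells by nuclear radius
#'
#' Cells whose nuclear radius strictly exceeds `max_radius_um` (default 5
#' microns, the expected upper bound for a real nucleus) are removed; larger
#' objects are typically segmentation artifacts merging several nuclei. When
#' no radius column is present the radius is derived from the nuclear area
#' assuming a circular nucleus, r = sqrt(area / pi); an explicit radius
#' column takes precedence. The exclusion report is attached as the
#' `"qc_report"` attribute and retrievable with [qc_report()].
#'
#' @param table A [cell_table()].
#' @param max_radius_um Exclusion threshold in microns (strict `>`).
#' @return The filtered `cell_table`, with a `qc_report` attribute.
#' @export
#' @examples
#' tab <- cell_table(data.frame(section_id = "s1", phenotype = "Excit",
#'                              nuclear_area = pi * c(4, 5, 6)^2))
#' filtered <- qc_filter_cells(tab)
#' qc_report(filtered)
qc_filter_cells <- function(table, max_radius_um = 5) {
  stopifnot(inherits(table, "cell_table"))
  if (nrow(table) == 0) {
    out <- table
    attr(out, "qc_report") <- tibble(n_total = 0L, n_excluded = 0L,
                                     fraction_excluded = 0)
    return(out)
  }
  if ("radius" %in% names(table) && !all(is.na(table$radius))) {
    r <- table$radius
    # explicit radius wins; fall back to area-derived where missing
    r[is.na(r)] <- sqrt(table$nuclear_area[is.na(r)] / pi)
  } else if ("nuclear_area" %in% names(table)) {
    r <- sqrt(table$nuclear_area / pi)
  } else {
    stop("neither `radius` nor `nuclear_area` available", call. = FALSE)
  }
  # strict exclusion of radius > threshold; the relative epsilon absorbs
  # rounding in exported areas (two decimals of um^2 shift a derived
  # radius near 5 um by ~3e-5 relative)
  keep <- r <= max_radius_um * (1 + 1e-4)
  out <- table[keep, ]
  class(out) <- class(table)
  attr(out, "qc_report") <- tibble(
    n_total = nrow(table),
    n_excluded = sum(!keep),
    fraction_excluded = sum(!keep) / nrow(table)
  )
  out
}

#' Retrieve the exclusion report attached by [qc_filter_cells()]
#' @param table A filtered `cell_table`.
#' @return Tibble with `n_total`, `n_excluded`, `fraction_excluded`.
#' @export
qc_report <- function(table) {
  rep <- attr(table, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; run qc_filter_cells() first",
                         call. = FALSE)
  rep
}

#' Per-section cell-type composition from segmentation counts
#'
#' The measured proportion of each phenotype in a tissue section is the
#' number of nuclei with that label divided by the total number of nuclei
#' segmented in the section; unphenotyped (`"Other"`) cells count toward the
#' denominator. Filtering ([qc_filter_cells()]) is expected to precede this
#' step, matching the measurement procedure the package benchmarks against.
#'
#' @param table A [cell_table()].
#' @param by Column defining the section/sample grouping.
#' @return A `composition_table` tibble with columns `section_id`,
#'   `combination`, `cell_type`, `n_cells`, `n_total`, `proportion`.
#' @export
compute_proportions <- function(table, by = "section_id") {
  stopifnot(inherits(table, "cell_table"))
  if (nrow(table) == 0) stop("empty cell table", call. = FALSE)
  comp <- table %>%
    count(section_id = .data[[by]], combination = .data$combination,
          cell_type = .data$phenotype, name = "n_cells") %>%
    group_by(.data$section_id) %>%
    mutate(n_total = sum(.data$n_cells),
           proportion = .data$n_cells / .data$n_total) %>%
    ungroup()
  composition_table(comp)
}

#' Construct/validate a composition table
#'
#' Long-format table of orthogonally measured per-section cell-type
#' proportions. Proportions must sum to 1 within each section.
#'
#' @param df Data frame with `section_id`, `cell_type`, `proportion` and
#'   optionally `n_cells`, `n_total`, `combination`.
#' @return A `composition_table` tibble.
#' @export
composition_table <- function(df) {
  df <- as_tibble(df)
  needed <- c("section_id", "cell_type", "proportion")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("composition table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sums <- tapply(df$proportion, df$section_id, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("proportions must sum to 1 per section (worst deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  class(df) <- c("composition_table", class(tibble()))
  df
}

#' Merge cell-type columns (e.g. Oligo + OPC -> OligoOPC)
#'
#' Imaging assays often cannot distinguish closely related types, so
#' predicted proportions are collapsed before comparison: the merged type's
#' proportion is the sum of its sources and row sums are preserved. Works on
#' both long [composition_table()]s and wide [proportion_table()]s; a
#' single-source mapping is a rename.
#'
#' @param x A `composition_table` or `proportion_table`.
#' @param mapping Named list, e.g. `list(OligoOPC = c("Oligo", "OPC"))`.
#' @return Object of the same class with types merged.
#' @export
merge_types <- function(x, mapping = list(OligoOPC = c("Oligo", "OPC"))) {
  UseMethod("merge_types")
}

#' @export
merge_types.composition_table <- function(x, mapping = list(OligoOPC = c("Oligo", "OPC"))) {
  df <- as_tibble(x)
  for (new in names(mapping)) {
    olds <- mapping[[new]]
    check_merge_collision(unique(df$cell_type), new, olds)
    absent <- setdiff(olds, unique(df$cell_type))
    if (length(absent) > 0) {
      warning("source type(s) absent, treated as 0: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
    df$cell_type[df$cell_type %in% olds] <- new
  }
  num <- intersect(c("n_cells", "proportion"), names(df))
  df <- df %>%
    group_by(across(-all_of(num))) %>%
    summarise(across(all_of(num), sum), .groups = "drop")
  composition_table(df)
}

#' @export
merge_types.proportion_table <- function(x, mapping = list(OligoOPC = c("Oligo", "OPC"))) {
  df <- as_tibble(x)
  types <- setdiff(names(df), "sample")
  for (new in names(mapping)) {
    olds <- mapping[[new]]
    check_merge_collision(types, new, olds)
    present <- intersect(olds, types)
    if (length(present) < length(olds)) {
      warning("source type(s) absent, treated as 0: ",
              paste(setdiff(olds, present), collapse = ", "), call. = FALSE)
    }
    df[[new]] <- if (length(present) > 0) {
      rowSums(as.matrix(df[, present, drop = FALSE]))
    } else {
      0
    }
    df <- df[, setdiff(names(df), setdiff(present, new)), drop = FALSE]
    types <- setdiff(names(df), "sample")
  }
  proportion_table(df, method = attr(x, "method"),
                   gene_set = attr(x, "gene_set"))
}

check_merge_collision <- function(types, new, olds) {
  if (new %in% setdiff(types, olds)) {
    stop("merged name '", new, "' collides with an existing unmapped type",
         call. = FALSE)
  }
}

#' Per-type cell-size metrics from a segmentation table
#'
#' Summarises each phenotype's physical size three ways: the median nuclear
#' area, the median copy number of the total-RNA marker gene, and the median
#' of the per-cell product area x copies. All three are candidate cell-size
#' inputs for size-aware deconvolution ([adjust_for_cell_size()]). The
#' product is computed per cell before taking the median, not as a product
#' of medians. Run after [qc_filter_cells()].
#'
#' @param table A [cell_table()] with `treg_copies` (types lacking it yield
#'   `NA` in the copy-based metrics).
#' @return A tibble with one row per phenotype: `cell_type`, `n_cells`,
#'   `median_area`, `median_copies`, `median_area_x_copies`.
#' @export
cell_size_metrics <- function(table) {
  stopifnot(inherits(table, "cell_table"))
  if (!"treg_copies" %in% names(table)) table$treg_copies <- NA_real_
  table %>%
    as_tibble() %>%
    group_by(cell_type = .data$phenotype) %>%
    summarise(
      n_cells = dplyr::n(),
      median_area = median(.data$nuclear_area),
      median_copies = median(as.numeric(.data$treg_copies)),
      median_area_x_copies = median(.data$nuclear_area *
                                      as.numeric(.data$treg_copies)),
      .groups = "drop"
    )
}
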
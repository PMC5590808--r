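# Typed survey tables, CSV I/O, validation and record-level filters.
#
# All linear dimensions are stored in millimetres and all masses in grams;
# plot sides keep the units of the field protocol (cm for stone quadrats,
# m for snail transect plots).

.table_kinds <- c("tools", "stone_quadrats", "snail_transects", "prey_sizes",
                  "maturation", "island_profiles", "consumption_rates")

# required / optional columns, and which must parse as numbers
.schemas <- list(
  tools = list(
    required = c("island", "task", "weight_g"),
    optional = c("tool_id", "length_mm", "width_mm", "depth_mm",
                 "user_id", "user_class", "provenance"),
    numeric  = c("weight_g", "length_mm", "width_mm", "depth_mm")
  ),
  stone_quadrats = list(
    required = c("island", "location_index", "zone", "stone_weight_g"),
    optional = c("stone_length_mm", "stone_width_mm"),
    numeric  = c("location_index", "stone_weight_g", "stone_length_mm",
                 "stone_width_mm")
  ),
  snail_transects = list(
    required = c("island", "transect_index", "species", "count"),
    optional = character(),
    numeric  = c("transect_index", "count")
  ),
  prey_sizes = list(
    required = c("island", "taxon", "length_mm", "width_mm"),
    optional = c("weight_g", "derived_size"),
    numeric  = c("length_mm", "width_mm", "weight_g", "derived_size")
  ),
  maturation = list(
    required = c("island", "species", "size_category", "shell_size_mm",
                 "stage"),
    optional = character(),
    numeric  = c("size_category", "shell_size_mm", "stage")
  ),
  island_profiles = list(
    required = c("island", "n_tool_users", "accessible_shoreline_m"),
    optional = c("strip_width_m", "group_size", "area_km2"),
    numeric  = c("n_tool_users", "accessible_shoreline_m", "strip_width_m",
                 "group_size", "area_km2")
  ),
  consumption_rates = list(
    required = c("oysters_per_day", "periwinkles_per_hour", "other_per_day"),
    optional = c("foraging_hours_per_day", "days_per_year",
                 "total_items_per_day"),
    numeric  = c("oysters_per_day", "periwinkles_per_hour", "other_per_day",
                 "foraging_hours_per_day", "days_per_year",
                 "total_items_per_day")
  )
)

coerce_numeric_col <- function(df, col, kind) {
  x <- df[[col]]
  if (is.numeric(x)) return(df)
  parsed <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(parsed))
  if (length(bad))
    stop("table '", kind, "': column '", col, "' is not numeric at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  df[[col]] <- parsed
  df
}

validate_table <- function(df, kind) {
  sch <- .schemas[[kind]]
  if (is.null(sch)) stop("unknown table kind: ", kind, call. = FALSE)
  missing <- setdiff(sch$required, names(df))
  if (length(missing))
    stop("table '", kind, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c(sch$required, sch$optional))
  if (length(extra)) {
    warning("table '", kind, "': ignoring unknown column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[setdiff(names(df), extra)]
  }
  for (col in intersect(sch$numeric, names(df)))
    df <- coerce_numeric_col(df, col, kind)
  if ("island" %in% names(df))
    df$island <- as.character(check_island(df$island))

  if (nrow(df)) {
    if (kind == "tools") {
      bad <- setdiff(unique(df$task), c("oyster", "snail"))
      if (length(bad)) stop("tools: unknown task(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      if (any(!is.finite(df$weight_g) | df$weight_g <= 0))
        stop("tools: weight_g must be > 0 (offending row(s): ",
             paste(utils::head(which(!is.finite(df$weight_g) |
                                       df$weight_g <= 0), 5), collapse = ", "),
             ")", call. = FALSE)
    }
    if (kind == "stone_quadrats") {
      bad <- setdiff(unique(df$zone), c("oyster_bed", "tidal"))
      if (length(bad)) stop("stone_quadrats: unknown zone(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      if (any(df$stone_weight_g < 0))
        stop("stone_quadrats: negative stone weights", call. = FALSE)
    }
    if (kind == "snail_transects") {
      bad <- setdiff(unique(df$species), snail_species())
      if (length(bad)) stop("snail_transects: unknown species: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      if (any(df$count < 0)) stop("snail_transects: negative counts",
                                  call. = FALSE)
    }
    if (kind == "prey_sizes") {
      bad <- setdiff(unique(df$taxon), prey_taxa())
      if (length(bad)) stop("prey_sizes: unknown taxon: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      if (any(df$length_mm <= 0 | df$width_mm <= 0))
        stop("prey_sizes: dimensions must be > 0", call. = FALSE)
    }
    if (kind == "maturation") {
      if (any(!df$stage %in% 1:4) || any(!df$size_category %in% 1:4))
        stop("maturation: stage and size_category must be in 1..4",
             call. = FALSE)
      if (any(df$shell_size_mm <= 0))
        stop("maturation: shell_size_mm must be > 0", call. = FALSE)
    }
    if (kind == "island_profiles") {
      if (any(df$n_tool_users < 1))
        stop("island_profiles: n_tool_users must be >= 1", call. = FALSE)
      if (any(df$accessible_shoreline_m < 0))
        stop("island_profiles: negative shoreline", call. = FALSE)
    }
  }
  df
}

#' Bundle validated survey tables into one dataset
#'
#' A `survey_dataset` is a named list of data frames, one per survey table
#' kind (`tools`, `stone_quadrats`, `snail_transects`, `prey_sizes`,
#' `maturation`, `island_profiles`, `consumption_rates`). Any subset of
#' tables may be present; every present table is validated against its
#' schema.
#'
#' @param ... Named data frames among the table kinds above.
#' @return A `survey_dataset` object.
#' @export
survey_dataset <- function(...) {
  tabs <- list(...)
  bad <- setdiff(names(tabs), .table_kinds)
  if (length(bad)) stop("unknown table kind(s): ", paste(bad, collapse = ", "))
  out <- stats::setNames(vector("list", length(.table_kinds)), .table_kinds)
  for (k in names(tabs))
    if (!is.null(tabs[[k]])) out[[k]] <- validate_table(tabs[[k]], k)
  structure(out, class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  for (k in .table_kinds) {
    if (is.null(x[[k]])) next
    cat(sprintf("  %-18s %d rows\n", k, nrow(x[[k]])))
  }
  invisible(x)
}

#' Read survey CSV tables into a validated dataset
#'
#' Each file must be UTF-8 CSV with a header row, decimal point `.` and no
#' thousands separators. Missing required columns raise a schema error
#' naming the column; non-numeric values in numeric columns raise a
#' row-level parse error; island labels outside the two study islands raise
#' a validation error. Unknown extra columns are dropped with a warning.
#'
#' @param paths Named character vector or list of file paths; names must be
#'   among the table kinds (see [survey_dataset()]). Tables not listed are
#'   simply absent from the result.
#' @return A [survey_dataset()].
#' @seealso [write_survey_tables()]
#' @export
read_survey_tables <- function(paths) {
  paths <- unlist(paths)
  bad <- setdiff(names(paths), .table_kinds)
  if (length(bad)) stop("unknown table kind(s): ", paste(bad, collapse = ", "))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("file(s) not found: ", paste(missing, collapse = ", "))
  tabs <- lapply(paths, function(p)
    utils::read.csv(p, stringsAsFactors = FALSE, fileEncoding = "UTF-8"))
  do.call(survey_dataset, tabs)
}

#' Write a survey dataset back to CSV files
#'
#' Inverse of [read_survey_tables()]: writing then reading reproduces the
#' dataset exactly (round-trip identity), so synthetic and field data are
#' interchangeable on disk.
#'
#' @param dataset A [survey_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_survey_tables <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character()
  for (k in .table_kinds) {
    if (is.null(dataset[[k]])) next
    path <- file.path(dir, paste0(k, ".csv"))
    utils::write.csv(dataset[[k]], path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    out[k] <- path
  }
  invisible(out)
}

#' Filter quadrat stones down to plausible tool candidates
#'
#' The field protocol discards stones too small to serve as tools: a stone
#' is retained when its weight is at least 80% of the smallest tool known to
#' be used on the high-predation island (i.e. stones more than 20% lighter
#' than that tool are excluded), and no dimension exceeds the quadrat side.
#' The filter preserves row order and is idempotent.
#'
#' @param stones Data frame with a weight column (`weight_g` or
#'   `stone_weight_g`) and optional length/width columns (`length_mm` /
#'   `stone_length_mm`, etc.).
#' @param min_tool_weight_g Weight of the smallest observed tool (> 0), g.
#' @param plot_side_mm Quadrat side length in mm (default 200, a 20 cm
#'   square plot). Stones with a recorded dimension above this cannot have
#'   come from inside the plot.
#' @return The filtered data frame, attributes `n_dropped` recording how
#'   many rows were removed.
#' @examples
#' s <- data.frame(weight_g = c(10, 7.9, 8.0))
#' filter_candidate_stones(s, min_tool_weight_g = 10)  # keeps 10 and 8.0
#' @export
filter_candidate_stones <- function(stones, min_tool_weight_g,
                                    plot_side_mm = 200) {
  check_number(min_tool_weight_g, "min_tool_weight_g", 0, strict = TRUE)
  wcol <- intersect(c("weight_g", "stone_weight_g"), names(stones))[1]
  if (is.na(wcol)) stop("stones must have a weight_g or stone_weight_g column")
  w <- stones[[wcol]]
  if (any(is.na(w)) || any(w < 0)) stop("stone weights must be nonnegative")
  keep <- w >= 0.8 * min_tool_weight_g
  for (dim in c("length_mm", "width_mm", "stone_length_mm", "stone_width_mm")) {
    if (dim %in% names(stones)) {
      d <- stones[[dim]]
      keep <- keep & (is.na(d) | d <= plot_side_mm)
    }
  }
  out <- stones[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Derived prey size from shell dimensions
#'
#' Oyster size is the length x width rectangle area (mm^2); snail size is
#' the volume of a cone with the shell width as base diameter and the shell
#' length as height (mm^3), a standard proxy for turbinate shells:
#' \deqn{V = \tfrac{1}{3}\pi (w/2)^2 \ell .}
#' `length_only` falls back to the raw shell length (mm) when width was not
#' recorded.
#'
#' @param length_mm,width_mm Shell dimensions in mm (vectorised).
#'   `width_mm` may be `NULL` for method `length_only`.
#' @param method One of `"oyster_area"`, `"snail_volume"`, `"length_only"`.
#' @return Numeric vector of derived sizes; strictly increasing in each
#'   dimension for a fixed method.
#' @examples
#' compute_prey_size(20, 10, "oyster_area")   # 200
#' compute_prey_size(12, 6, "snail_volume")   # (1/3) * pi * 9 * 12
#' @export
compute_prey_size <- function(length_mm, width_mm = NULL,
                              method = c("oyster_area", "snail_volume",
                                         "length_only")) {
  method <- match.arg(method)
  if (any(is.na(length_mm)))
    stop("method '", method, "' requires length_mm for every record")
  if (method == "length_only") return(length_mm)
  if (is.null(width_mm) || any(is.na(width_mm)))
    stop("method '", method, "' requires width_mm for every record")
  switch(method,
    oyster_area  = length_mm * width_mm,
    snail_volume = (1 / 3) * pi * (width_mm / 2)^2 * length_mm
  )
}

#' Attach derived sizes to a prey-size table
#'
#' Applies the taxon-appropriate size proxy (`oyster_area` for oysters,
#' `snail_volume` for snails) and stores it in a `derived_size` column.
#'
#' @param sizes A `prey_sizes` data frame.
#' @return The data frame with a `derived_size` column.
#' @export
add_derived_size <- function(sizes) {
  sizes <- validate_table(sizes, "prey_sizes")
  method <- ifelse(sizes$taxon == "oyster", "oyster_area", "snail_volume")
  sizes$derived_size <- ifelse(
    method == "oyster_area",
    compute_prey_size(sizes$length_mm, sizes$width_mm, "oyster_area"),
    compute_prey_size(sizes$length_mm, sizes$width_mm, "snail_volume"))
  sizes
}

#' Construct an island profile
#'
#' Shoreline geometry and tool-user head count for one island, the inputs
#' of the foraging-area and depletion calculations.
#'
#' @param island Island name.
#' @param n_tool_users Number of tool-using individuals (>= 1).
#' @param accessible_shoreline_m Length of shoreline suitable for shellfish
#'   foraging, metres.
#' @param strip_width_m Average width of the foraging strip, metres
#'   (default 3).
#' @param group_size Total group size (optional).
#' @param area_km2 Island area in km^2 (optional).
#' @return A one-row `island_profiles` data frame.
#' @export
island_profile <- function(island, n_tool_users, accessible_shoreline_m,
                           strip_width_m = 3, group_size = NA,
                           area_km2 = NA) {
  check_number(n_tool_users, "n_tool_users", 1)
  check_number(accessible_shoreline_m, "accessible_shoreline_m", 0)
  check_number(strip_width_m, "strip_width_m", 0, strict = TRUE)
  validate_table(data.frame(
    island = island, n_tool_users = n_tool_users,
    accessible_shoreline_m = accessible_shoreline_m,
    strip_width_m = strip_width_m, group_size = group_size,
    area_km2 = area_km2, stringsAsFactors = FALSE), "island_profiles")
}

#' Construct per-individual consumption rates
#'
#' Daily and hourly intake rates of one tool-using forager. The defaults are
#' the observed rates on the high-predation island: 36 rock oysters and 8.9
#' other items per day, 1.6 tropical periwinkles per foraging hour over a
#' 4-hour daily foraging window, 46.5 items per day in total.
#'
#' @param oysters_per_day Rock oysters eaten per day.
#' @param periwinkles_per_hour Periwinkles eaten per foraging hour.
#' @param other_per_day Other shellfish items per day.
#' @param foraging_hours_per_day Daily foraging window, hours (default 4).
#' @param days_per_year Foraging days per year (default 365).
#' @param total_items_per_day Total daily intake (default 46.5).
#' @return A one-row `consumption_rates` data frame.
#' @export
consumption_rates <- function(oysters_per_day = 36, periwinkles_per_hour = 1.6,
                              other_per_day = 8.9, foraging_hours_per_day = 4,
                              days_per_year = 365, total_items_per_day = 46.5) {
  df <- data.frame(oysters_per_day = oysters_per_day,
                   periwinkles_per_hour = periwinkles_per_hour,
                   other_per_day = other_per_day,
                   foraging_hours_per_day = foraging_hours_per_day,
                   days_per_year = days_per_year,
                   total_items_per_day = total_items_per_day)
  if (any(unlist(df) < 0)) stop("consumption rates must be >= 0")
  validate_table(df, "consumption_rates")
}
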
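#' Square analysis grid
#'
#' Defines a regular grid of square cells over the planar study region.
#' Cells are half-open: a point on a cell's lower or left edge belongs to
#' that cell; a point exactly on the shared edge belongs to the higher-index
#' cell.
#'
#' @param origin_x_km,origin_y_km planar coordinates of the grid's lower-left
#'   corner (km).
#' @param cell_size_km cell edge length in km (default 20, the resolution
#'   commonly used for subterranean richness mapping).
#' @param n_cols,n_rows grid dimensions.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x_km, origin_y_km, cell_size_km = 20,
                      n_cols, n_rows) {
  stop_if_not_scalar_number(cell_size_km, "cell_size_km")
  if (cell_size_km <= 0) stop("`cell_size_km` must be positive", call. = FALSE)
  if (n_cols < 1 || n_rows < 1) stop("grid must have at least one cell", call. = FALSE)
  structure(
    list(origin_x_km = origin_x_km, origin_y_km = origin_y_km,
         cell_size_km = cell_size_km,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d x %d cells of %g km, origin (%g, %g) km\n",
              x$n_cols, x$n_rows, x$cell_size_km, x$origin_x_km, x$origin_y_km))
  invisible(x)
}

#' Grid covering a set of records
#'
#' Convenience constructor: a grid whose origin sits on multiples of
#' `cell_size_km` below the in-study-area records and which covers them all.
#'
#' @param records occurrence data.frame; only rows with
#'   `in_study_area = TRUE` (if the column exists) are covered.
#' @param cell_size_km cell edge length in km.
#' @return a [grid_spec()].
#' @export
make_grid <- function(records, cell_size_km = 20) {
  .check_records(records)
  keep <- if ("in_study_area" %in% names(records)) records$in_study_area else TRUE
  x <- records$x_km[keep]
  y <- records$y_km[keep]
  if (length(x) == 0L) stop("no in-study-area records to cover", call. = FALSE)
  ox <- floor(min(x) / cell_size_km) * cell_size_km
  oy <- floor(min(y) / cell_size_km) * cell_size_km
  grid_spec(ox, oy, cell_size_km,
            n_cols = floor((max(x) - ox) / cell_size_km) + 1L,
            n_rows = floor((max(y) - oy) / cell_size_km) + 1L)
}

#' Assign occurrence records to grid cells
#'
#' Maps each record to a cell via `floor((coord - origin)/cell_size)` under
#' the half-open convention. Records flagged `in_study_area = FALSE`, or
#' falling outside the grid extent, get `NA` ("outside") and are excluded
#' from richness surfaces.
#'
#' @param records occurrence data.frame.
#' @param grid a [grid_spec()].
#' @return data.frame with one row per record: `col`, `row` (1-based) and
#'   `cell_id` (`NA` for outside records).
#' @export
assign_cells <- function(records, grid) {
  .check_records(records)
  stopifnot(inherits(grid, "grid_spec"))
  col <- floor((records$x_km - grid$origin_x_km) / grid$cell_size_km) + 1
  row <- floor((records$y_km - grid$origin_y_km) / grid$cell_size_km) + 1
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  if ("in_study_area" %in% names(records)) {
    inside <- inside & records$in_study_area
  }
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(
    col = as.integer(col),
    row = as.integer(row),
    cell_id = ifelse(inside, sprintf("c%d_%d", as.integer(col), as.integer(row)),
                     NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Species richness surface
#'
#' Per-cell species sets and counts over the occupied cells of a grid
#' (cells without records are excluded, as is standard for point-mapped
#' atlas data). A species recorded at several localities within one cell
#' counts once.
#'
#' @param records occurrence data.frame.
#' @param grid a [grid_spec()].
#' @return an object of class `richness_surface`: list with `grid`, `cells`
#'   (data.frame `cell_id`, `col`, `row`, `center_x_km`, `center_y_km`,
#'   `richness`), `species` (named list cell_id -> character vector of
#'   species), and `r_max`.
#' @export
richness_surface <- function(records, grid) {
  asg <- assign_cells(records, grid)
  keep <- !is.na(asg$cell_id)
  if (!any(keep)) stop("no records fall inside the grid", call. = FALSE)
  cell_sp <- lapply(
    split(records$species_id[keep], asg$cell_id[keep]),
    function(s) sort(unique(s))
  )
  ids <- names(cell_sp)
  cr <- do.call(rbind, strsplit(sub("^c", "", ids), "_"))
  col <- as.integer(cr[, 1L])
  row <- as.integer(cr[, 2L])
  cells <- data.frame(
    cell_id = ids,
    col = col,
    row = row,
    center_x_km = grid$origin_x_km + (col - 0.5) * grid$cell_size_km,
    center_y_km = grid$origin_y_km + (row - 0.5) * grid$cell_size_km,
    richness = vapply(cell_sp, length, integer(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(grid = grid, cells = cells, species = cell_sp,
         r_max = max(cells$richness)),
    class = "richness_surface"
  )
}

#' @export
print.richness_surface <- function(x, ...) {
  cat(sprintf("Richness surface: %d occupied cells, richest cell holds %d species\n",
              nrow(x$cells), x$r_max))
  invisible(x)
}

#' Classify cells into five richness classes
#'
#' Cells are binned relative to the richest cell's richness `r_max`:
#' class 1 (> 85%), class 2 (60--85%), class 3 (40--<60%),
#' class 4 (20--<40%), class 5 (< 20%). Only the 85% bound is strict;
#' the 60/40/20 bounds are inclusive from below. With `r_max` 14 this puts
#' the class-1 minimum at 12 species and the class-1-or-2 minimum at 9; with
#' `r_max` 22, at 19 and 14.
#'
#' @param surface a [richness_surface()].
#' @param thresholds the four class-boundary fractions, descending.
#' @return object of class `richness_classification`: the surface plus a
#'   `class` column in `$cells` and `$thresholds`.
#' @export
classify_richness <- function(surface, thresholds = c(0.85, 0.60, 0.40, 0.20)) {
  stopifnot(inherits(surface, "richness_surface"))
  if (length(thresholds) != 4L || is.unsorted(rev(thresholds))) {
    stop("`thresholds` must be four descending fractions", call. = FALSE)
  }
  r <- surface$cells$richness
  rmax <- surface$r_max
  cls <- ifelse(r > thresholds[1] * rmax, 1L,
         ifelse(r >= thresholds[2] * rmax, 2L,
         ifelse(r >= thresholds[3] * rmax, 3L,
         ifelse(r >= thresholds[4] * rmax, 4L, 5L))))
  out <- surface
  out$cells$class <- cls
  out$thresholds <- thresholds
  class(out) <- c("richness_classification", "richness_surface")
  out
}

#' Hotspot cells (richness class 1)
#'
#' @param classification a [classify_richness()] result.
#' @return character vector of cell ids with richness above 85% of the
#'   richest cell.
#' @export
hotspots <- function(classification) {
  stopifnot(inherits(classification, "richness_classification"))
  classification$cells$cell_id[classification$cells$class == 1L]
}

#' Species-rich cells (classes 1-2)
#'
#' @param classification a [classify_richness()] result.
#' @return character vector of cell ids holding at least 60% of the richest
#'   cell's species count.
#' @export
srcs <- function(classification) {
  stopifnot(inherits(classification, "richness_classification"))
  classification$cells$cell_id[classification$cells$class <= 2L]
}

#' Compare two richness surfaces
#'
#' Kendall tau-b rank correlation between two taxa's per-cell richness over a
#' shared grid, with a tie-corrected normal-approximation two-sided p-value.
#' Suited to integer richness with many repeated values.
#'
#' @param surface_a,surface_b [richness_surface()] objects on the same grid.
#' @param cells `"union"` (default): all cells occupied by either taxon, the
#'   other taxon's richness filled with 0; `"intersection"`: only cells
#'   occupied by both.
#' @return list with `tau_b`, `p_value`, `n_cells`.
#' @export
compare_surfaces <- function(surface_a, surface_b,
                             cells = c("union", "intersection")) {
  cells <- match.arg(cells)
  stopifnot(inherits(surface_a, "richness_surface"),
            inherits(surface_b, "richness_surface"))
  if (!identical(unclass(surface_a$grid), unclass(surface_b$grid))) {
    stop("surfaces must share a grid", call. = FALSE)
  }
  ra <- stats::setNames(surface_a$cells$richness, surface_a$cells$cell_id)
  rb <- stats::setNames(surface_b$cells$richness, surface_b$cells$cell_id)
  ids <- if (cells == "union") {
    union(names(ra), names(rb))
  } else {
    intersect(names(ra), names(rb))
  }
  if (length(ids) < 3L) stop("fewer than 3 shared cells", call. = FALSE)
  a <- ifelse(is.na(ra[ids]), 0L, ra[ids])
  b <- ifelse(is.na(rb[ids]), 0L, rb[ids])
  kt <- kendall_test(a, b)
  list(tau_b = kt$tau_b, p_value = kt$p_value, n_cells = length(ids))
}

#' Rarity-quartile composition of species-rich cells
#'
#' For every species-rich cell (SRC), the percentage of its species falling
#' in each rarity quartile, plus the across-SRC mean and min-max range per
#' quartile. Quartile 1 is "rare", quartile 4 "common".
#'
#' @param classification a [classify_richness()] result.
#' @param quartiles data.frame with `species_id` and `rarity_quartile`
#'   (e.g. from [assign_quartiles()]), covering every species present in
#'   the SRCs.
#' @return list of class `src_composition`: `per_cell` (one row per SRC,
#'   columns `cell_id`, `richness`, `pct_q1`..`pct_q4`) and `summary`
#'   (per quartile: `mean_pct`, `min_pct`, `max_pct`).
#' @export
src_composition <- function(classification, quartiles) {
  src_ids <- srcs(classification)
  if (length(src_ids) == 0L) stop("no species-rich cells", call. = FALSE)
  qmap <- stats::setNames(quartiles$rarity_quartile, quartiles$species_id)
  per_cell <- do.call(rbind, lapply(src_ids, function(id) {
    sp <- classification$species[[id]]
    q <- qmap[sp]
    if (anyNA(q)) {
      stop("species without a rarity quartile in cell ", id, call. = FALSE)
    }
    shares <- 100 * tabulate(q, nbins = 4L) / length(sp)
    data.frame(cell_id = id, richness = length(sp),
               pct_q1 = shares[1], pct_q2 = shares[2],
               pct_q3 = shares[3], pct_q4 = shares[4],
               stringsAsFactors = FALSE)
  }))
  mat <- as.matrix(per_cell[, c("pct_q1", "pct_q2", "pct_q3", "pct_q4")])
  summary <- data.frame(
    quartile = 1:4,
    mean_pct = colMeans(mat),
    min_pct = apply(mat, 2, min),
    max_pct = apply(mat, 2, max),
    row.names = NULL
  )
  structure(list(per_cell = per_cell, summary = summary),
            class = "src_composition")
}

#' @export
print.src_composition <- function(x, ...) {
  cat(sprintf("Quartile composition of %d species-rich cells\n", nrow(x$per_cell)))
  with(x$summary, cat(sprintf(
    "  q%d: mean %.0f%% (range %.0f%%-%.0f%%)\n", quartile, mean_pct, min_pct, max_pct
  )))
  invisible(x)
}

#' Export a richness surface or classification as a delimited table
#'
#' @param surface a [richness_surface()] or [classify_richness()] result.
#' @param path output file path (CSV).
#' @return the written data.frame, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "richness_surface"))
  utils::write.csv(surface$cells, path, row.names = FALSE)
  invisible(surface$cells)
}

#' Export grid cells as GeoJSON polygons
#'
#' Writes occupied cells as square polygon features (planar km coordinates)
#' with richness and, when present, class attributes — convenient for quick
#' mapping in GIS tools.
#'
#' @param surface a [richness_surface()] or classification.
#' @param path output file path (.geojson).
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(surface, path) {
  stopifnot(inherits(surface, "richness_surface"))
  g <- surface$grid
  s <- g$cell_size_km
  feats <- lapply(seq_len(nrow(surface$cells)), function(i) {
    ce <- surface$cells[i, ]
    x0 <- g$origin_x_km + (ce$col - 1) * s
    y0 <- g$origin_y_km + (ce$row - 1) * s
    props <- list(cell_id = ce$cell_id, richness = ce$richness)
    if (!is.null(ce$class)) props$class <- ce$class
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(list(
          c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s), c(x0, y0)
        ))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
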
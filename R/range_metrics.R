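#' Maximum linear extent of a set of points
#'
#' Range size measured as the largest Euclidean distance between any two
#' occurrence points, on projected planar coordinates in km. A single point
#' has extent 0. One-dimensional by design: no convex hulls or areas.
#'
#' @param x,y numeric vectors of planar coordinates (km).
#' @return length in km (scalar).
#' @examples
#' max_linear_extent(c(0, 3), c(0, 4)) # 5
#' @export
max_linear_extent <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("empty point set", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (length(x) == 1L) return(0)
  max(stats::dist(cbind(x, y)))
}

#' Per-species range-size profiles
#'
#' Builds the species profile table: number of distinct localities, maximum
#' linear extent (MLE), and (when a grid is supplied) number of occupied grid
#' cells. MLE uses all records of a species, including those flagged outside
#' the study area -- range size is a property of the species, while gridding
#' later uses only in-area records.
#'
#' @param records occurrence data.frame (`species_id`, `locality_id`, `x_km`,
#'   `y_km`, optionally `in_study_area`).
#' @param grid optional [grid_spec()]; adds `n_occupied_cells`.
#' @return data.frame with `species_id`, `n_localities`, `mle_km` and
#'   optionally `n_occupied_cells`, one row per species.
#' @export
species_profiles <- function(records, grid = NULL) {
  .check_records(records)
  sp <- split(records, records$species_id)
  prof <- data.frame(
    species_id = names(sp),
    n_localities = vapply(sp, function(d) {
      nrow(unique(d[, c("x_km", "y_km")]))
    }, integer(1)),
    mle_km = vapply(sp, function(d) max_linear_extent(d$x_km, d$y_km), numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!is.null(grid)) {
    asg <- assign_cells(records, grid)
    occ <- tapply(asg$cell_id, records$species_id,
                  function(z) length(unique(z[!is.na(z)])))
    prof$n_occupied_cells <- as.integer(occ[prof$species_id])
  }
  prof
}

#' Range-size rarity quartiles
#'
#' Splits species into four rarity quartiles by MLE (quartile 1 = smallest
#' ranges, "rare"; quartile 4 = largest, "common"), keeping all species with
#' equal MLE in the same quartile. Species are sorted by MLE and cut at
#' nominal ranks n/4, n/2, 3n/4; a block of tied species straddling a cut
#' goes entirely to the side holding the majority of its members (an exact
#' half split goes to the lower quartile), and the remaining cut ranks are
#' then recomputed over the remaining species, so quartile sizes can be
#' unequal.
#'
#' @param profiles data.frame from [species_profiles()] (needs `species_id`,
#'   `mle_km`), or any data.frame with those columns.
#' @param tie_rule `"majority"` (default, described above; a block wider
#'   than a whole quartile stays in the lowest quartile it covers, so a
#'   dominant single-site block always forms quartile 1) or `"lower"`
#'   (a straddling block always joins the lower quartile).
#' @return `profiles` with an integer `rarity_quartile` column added.
#' @export
assign_quartiles <- function(profiles, tie_rule = c("majority", "lower")) {
  tie_rule <- match.arg(tie_rule)
  if (!all(c("species_id", "mle_km") %in% names(profiles))) {
    stop("`profiles` needs columns species_id and mle_km", call. = FALSE)
  }
  n <- nrow(profiles)
  if (n < 4L) stop("need at least 4 species to form quartiles", call. = FALSE)
  if (length(unique(profiles$mle_km)) < 4L) {
    stop("fewer than 4 distinct MLE values: no quartile structure", call. = FALSE)
  }
  ord <- order(profiles$mle_km)
  blocks <- rle(profiles$mle_km[ord])
  q_of_block <- .assign_tie_blocks(blocks$lengths, tie_rule)
  quart <- rep.int(q_of_block, blocks$lengths)
  out <- profiles
  out$rarity_quartile <- NA_integer_
  out$rarity_quartile[ord] <- quart
  if (length(unique(quart)) < 4L) {
    stop("tie blocks collapse the data into fewer than 4 quartiles", call. = FALSE)
  }
  out
}

# Walk tie blocks in MLE order, filling quartiles 1..4. Current quartile's
# target size is (species left)/(quartiles left); a block that overshoots
# stays whole in the quartile holding the plurality of its members (the
# current one when tied, so exact half splits go down). A block wider than a
# whole quartile therefore sits in the lowest quartile it covers fully.
# Returns one quartile label per block.
.assign_tie_blocks <- function(block_sizes, tie_rule) {
  n_blocks <- length(block_sizes)
  q <- integer(n_blocks)
  remaining <- sum(block_sizes)
  quart <- 1L
  left_q <- 4L
  target <- remaining / left_q
  filled <- 0
  for (b in seq_len(n_blocks)) {
    size <- block_sizes[b]
    in_range <- target - filled
    take <- if (filled + size <= target) {
      TRUE
    } else if (tie_rule == "lower") {
      TRUE
    } else {
      # plurality over the nominal quartile-width chunks the block spans;
      # the chunk beyond the current quartile holds at most
      # min(size - in_range, target) members
      in_range >= min(size - in_range, target)
    }
    if (!take && filled == 0) {
      stop("internal error: empty quartile during tie-block assignment",
           call. = FALSE)
    }
    if (take) {
      q[b] <- quart
      filled <- filled + size
      remaining <- remaining - size
      if (filled >= target && quart < 4L) {
        quart <- quart + 1L
        left_q <- left_q - 1L
        target <- remaining / left_q
        filled <- 0
      }
    } else {
      # close the current quartile and retry this block in the next one
      quart <- min(quart + 1L, 4L)
      left_q <- max(left_q - 1L, 1L)
      target <- remaining / left_q
      filled <- 0
      q[b] <- quart
      filled <- filled + size
      remaining <- remaining - size
      if (filled >= target && quart < 4L) {
        quart <- quart + 1L
        left_q <- left_q - 1L
        target <- remaining / left_q
        filled <- 0
      }
    }
  }
  q
}

#' Range-size frequency distribution summary
#'
#' Moment skewness of the MLE distribution, a per-quartile table (count,
#' percentage share, largest MLE) and the single-site endemic count and
#' share. Percentages are rounded to whole numbers for reporting.
#'
#' @param profiles data.frame with `mle_km` and (if not yet present)
#'   quartiles are computed via [assign_quartiles()].
#' @param skewness_type `"g1"` (plain moment coefficient, default) or `"G1"`
#'   (adjusted Fisher-Pearson).
#' @return a list of class `rsfd_summary`: `skewness`, `quartile_table`,
#'   `n_species`, `n_single_site`, `single_site_share`, `single_site_pct`.
#' @export
rsfd_summary <- function(profiles, skewness_type = c("g1", "G1")) {
  skewness_type <- match.arg(skewness_type)
  x <- profiles$mle_km
  if (length(x) < 3L) stop("need at least 3 species for skewness", call. = FALSE)
  if (!("rarity_quartile" %in% names(profiles))) {
    profiles <- assign_quartiles(profiles)
  }
  g1 <- skewness_coef(x, skewness_type)
  qt <- do.call(rbind, lapply(1:4, function(q) {
    xs <- x[profiles$rarity_quartile == q]
    data.frame(
      quartile = q,
      n = length(xs),
      share_pct = round(100 * length(xs) / length(x)),
      max_mle_km = if (length(xs)) max(xs) else NA_real_
    )
  }))
  n_single <- sum(x == 0)
  structure(
    list(
      skewness = g1,
      quartile_table = qt,
      n_species = length(x),
      n_single_site = n_single,
      single_site_share = n_single / length(x),
      single_site_pct = round(100 * n_single / length(x))
    ),
    class = "rsfd_summary"
  )
}

#' @export
print.rsfd_summary <- function(x, ...) {
  cat(sprintf("Range-size frequency distribution: %d species\n", x$n_species))
  cat(sprintf("  skewness %.2f; %d single-site endemics (%d%%)\n",
              x$skewness, x$n_single_site, x$single_site_pct))
  print(x$quartile_table, row.names = FALSE)
  invisible(x)
}

#' Moment skewness coefficient
#'
#' @param x numeric vector (length >= 3).
#' @param type `"g1"` = m3/m2^(3/2); `"G1"` = g1 * sqrt(n(n-1))/(n-2).
#' @return scalar skewness.
#' @export
skewness_coef <- function(x, type = c("g1", "G1")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance: skewness undefined", call. = FALSE)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  if (type == "G1") g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}
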
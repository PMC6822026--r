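# Moran's I correlogram, PCNM spatial filters, and filter selection for
# removing residual spatial autocorrelation from richness GLMs.

# Pairwise structure shared by the correlogram functions: pair indices,
# distances, and equal-pair-count class assignment.
.pair_classes <- function(coords, n_classes) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10L) stop("need at least 10 cells", call. = FALSE)
  d <- stats::dist(coords)
  np <- length(d)
  if (np < n_classes) stop("more classes than cell pairs; reduce n_classes", call. = FALSE)
  # equal-frequency classes: walk the distinct-distance blocks in order,
  # filling each class to (pairs left)/(classes left) -- ties in distance
  # never split across classes, so counts are as equal as the tie structure
  # permits (exactly equal +/-1 for continuous coordinates)
  dv <- sort(unique(as.numeric(d)))
  if (length(dv) < n_classes) {
    stop("a distance class holds zero pairs; reduce n_classes", call. = FALSE)
  }
  counts <- tabulate(match(as.numeric(d), dv), length(dv))
  block_class <- integer(length(dv))
  cls_i <- 1L
  left <- np
  left_classes <- n_classes
  filled <- 0
  for (b in seq_along(dv)) {
    # never leave fewer blocks than unfilled classes
    if (cls_i < n_classes &&
        (filled >= left / left_classes * 0.999 ||
         length(dv) - b < n_classes - cls_i)) {
      left <- left - filled
      left_classes <- left_classes - 1L
      cls_i <- cls_i + 1L
      filled <- 0
    }
    block_class[b] <- cls_i
    filled <- filled + counts[b]
  }
  cls <- block_class[match(as.numeric(d), dv)]
  hi <- vapply(seq_len(n_classes), function(k) max(dv[block_class == k]), numeric(1))
  bounds <- c(0, hi)
  # dist() runs column-major over the lower triangle: i = 1 pairs first
  ii <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)), use.names = FALSE)
  jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n), use.names = FALSE)
  list(i = ii, j = jj, d = as.numeric(d), class = cls, bounds = bounds,
       n = n, n_pairs_per_class = tabulate(cls, n_classes))
}

# Per-class Moran's I for one value vector given pair structure.
.moran_by_class <- function(z, pc, n_classes) {
  s2 <- sum(z^2)
  cross <- z[pc$i] * z[pc$j]
  s_class <- as.numeric(rowsum(cross, pc$class, reorder = TRUE))
  (pc$n / pc$n_pairs_per_class) * s_class / s2
}

#' Moran's I correlogram with permutation tests
#'
#' Spatial autocorrelation of a per-cell variable (typically GLM residuals)
#' at a set of distance classes whose bounds are chosen so each class holds
#' as near as possible the same number of cell pairs. Within class `c`,
#' binary weights connect exactly the pairs whose distance falls in the
#' class, and
#' \deqn{I_c = \frac{n}{S_0}\frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the centered values. Under no autocorrelation the
#' expectation is \eqn{-1/(n-1)}; significance is assessed by permuting the
#' values across cells, two-sided around that expectation, with the
#' +1/(R+1) correction.
#'
#' @param values numeric per-cell variable.
#' @param coords two-column matrix of cell center coordinates (km).
#' @param n_classes number of distance classes (default 14).
#' @param R number of permutations (default 10,000; reduce for quick runs).
#'   `R = 0` skips the test (p-values NA).
#' @param seed integer seed for the permutation stream.
#' @return object of class `correlogram`: data.frame with `class`,
#'   `d_lo_km`, `d_hi_km`, `n_pairs`, `I`, `expected_I`, `p_value`; the
#'   number of cells is kept in attribute `n`.
#' @export
morans_i_correlogram <- function(values, coords, n_classes = 14, R = 10000,
                                 seed = NULL) {
  coords <- as.matrix(coords)
  if (length(values) != nrow(coords)) {
    stop("`values` and `coords` must have matching length", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("constant values: Moran's I undefined", call. = FALSE)
  }
  pc <- .pair_classes(coords, n_classes)
  n <- pc$n
  z <- values - mean(values)
  I_obs <- .moran_by_class(z, pc, n_classes)
  e_i <- -1 / (n - 1)
  p <- rep(NA_real_, n_classes)
  if (R > 0) {
    exceed <- integer(n_classes)
    d_obs <- abs(I_obs - e_i)
    with_seed(seed, {
      for (r in seq_len(R)) {
        zp <- z[sample.int(n)]
        I_perm <- .moran_by_class(zp, pc, n_classes)
        exceed <- exceed + (abs(I_perm - e_i) >= d_obs)
      }
    })
    p <- (1 + exceed) / (R + 1)
  }
  structure(
    data.frame(
      class = seq_len(n_classes),
      d_lo_km = pc$bounds[-(n_classes + 1)],
      d_hi_km = pc$bounds[-1],
      n_pairs = pc$n_pairs_per_class,
      I = I_obs,
      expected_I = e_i,
      p_value = p
    ),
    n = n, R = R, class = c("correlogram", "data.frame")
  )
}

#' PCNM spatial filters (Moran eigenvector maps)
#'
#' Builds spatial eigenvector filters from cell-center coordinates: the
#' pairwise distance matrix is truncated (distances beyond `truncation_km`
#' replaced by `4 * truncation_km`), transformed to \eqn{-d^2/2}, Gower
#' double-centered, and eigendecomposed. The eigenvectors with positive
#' eigenvalues, ordered by descending eigenvalue, are the candidate spatial
#' filters: broad-scale structure first, fine-scale last. With 20-km cells a
#' truncation of 59 km links each cell to the two surrounding rings of
#' neighbors.
#'
#' @param coords two-column matrix of cell centers (km).
#' @param truncation_km truncation distance (default 59).
#' @return object of class `spatial_filters`: list with `vectors` (cells x
#'   filters, unit-norm columns), `values` (positive eigenvalues,
#'   descending), `truncation_km`, and `centered` (the double-centered
#'   matrix, for diagnostics).
#' @export
pcnm_filters <- function(coords, truncation_km = 59) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 cells", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  if (max(d) == 0) stop("all coordinates coincide", call. = FALSE)
  dt <- ifelse(d > truncation_km, 4 * truncation_km, d)
  a <- -dt^2 / 2
  rm_ <- rowMeans(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tol
  if (!any(pos)) stop("no positive eigenvalues: degenerate configuration", call. = FALSE)
  vec <- eig$vectors[, pos, drop = FALSE]
  colnames(vec) <- sprintf("filter_%d", seq_len(ncol(vec)))
  structure(
    list(vectors = vec, values = eig$values[pos],
         truncation_km = truncation_km, centered = g),
    class = "spatial_filters"
  )
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("%d PCNM spatial filters (truncation %g km), eigenvalues %.3g .. %.3g\n",
              ncol(x$vectors), x$truncation_km, x$values[1],
              x$values[length(x$values)]))
  invisible(x)
}

#' Select spatial filters to remove residual autocorrelation
#'
#' Forward selection of PCNM filters into a richness GLM, following the
#' three published criteria: candidate filters must correlate significantly
#' with the response; filters are added one at a time, each step choosing
#' the candidate whose inclusion most shrinks the largest deviation
#' \eqn{\max_c |I_c - E[I]|} of the refit model's residual correlogram; and
#' selection stops as soon as no correlogram class is significant at
#' `alpha` (autocorrelation removed) or candidates run out. Adding filters
#' can only decrease residual deviance, so the spatial model's pseudo
#' R-squared is at least the nonspatial one's.
#'
#' @param y per-cell response (overall richness).
#' @param x nonspatial predictors (matrix/data.frame/NULL).
#' @param filters a [pcnm_filters()] result.
#' @param coords cell-center coordinates used for the residual correlogram.
#' @param family GLM family, as in [fit_glm()].
#' @param alpha significance level both for the response-filter screening
#'   (Pearson) and for the correlogram stopping rule.
#' @param n_classes,R_perm,seed correlogram settings (permutations are only
#'   spent on the stopping tests, not on candidate scoring).
#' @param max_filters upper bound on the number of filters admitted before
#'   selection gives up (guards against chasing autocorrelation that the
#'   filter basis cannot absorb).
#' @return list of class `filter_selection`: `selected` (filter names),
#'   `fit` (spatial [fit_glm()]), `nonspatial_fit`, `correlogram` (residual
#'   correlogram of the final model), `status` (`"clean"` when
#'   autocorrelation was removed, `"exhausted"` with a warning otherwise,
#'   `"none_needed"` when the nonspatial residuals were already clean).
#' @export
select_filters <- function(y, x = NULL, filters, coords,
                           family = c("poisson", "negative_binomial"),
                           alpha = 0.05, n_classes = 14, R_perm = 1000,
                           seed = NULL, max_filters = 10L) {
  family <- match.arg(family)
  stopifnot(inherits(filters, "spatial_filters"))
  seeds <- derive_seeds(seed %||% 1L, ncol(filters$vectors) + 1L)
  base_x <- if (is.null(x)) NULL else as.data.frame(x)

  # criterion 3: keep only filters significantly correlated with the response
  cand <- which(vapply(seq_len(ncol(filters$vectors)), function(j) {
    stats::cor.test(y, filters$vectors[, j])$p.value < alpha
  }, logical(1)))

  fit0 <- fit_glm(y, base_x, family)
  bind_x <- function(sel) {
    fx <- as.data.frame(filters$vectors[, sel, drop = FALSE])
    if (is.null(base_x)) fx else cbind(base_x, fx)
  }
  resid_cgram <- function(fit, R, s) {
    morans_i_correlogram(fit$residuals, coords, n_classes, R, seed = s)
  }

  cg <- resid_cgram(fit0, R_perm, seeds[1])
  if (all(cg$p_value >= alpha, na.rm = TRUE)) {
    return(structure(
      list(selected = character(0), fit = fit0, nonspatial_fit = fit0,
           correlogram = cg, status = "none_needed"),
      class = "filter_selection"
    ))
  }

  selected <- integer(0)
  fit <- fit0
  step <- 1L
  while (length(cand) > 0 && length(selected) < max_filters) {
    # score candidates without permutations: max |I_c - E[I]| after refit
    scores <- vapply(cand, function(j) {
      f <- fit_glm(y, bind_x(c(selected, j)), family)
      cgj <- morans_i_correlogram(f$residuals, coords, n_classes, R = 0)
      max(abs(cgj$I - cgj$expected_I))
    }, numeric(1))
    best <- cand[which.min(scores)]
    selected <- c(selected, best)
    cand <- setdiff(cand, best)
    fit <- fit_glm(y, bind_x(selected), family)
    step <- step + 1L
    cg <- resid_cgram(fit, R_perm, seeds[step])
    if (all(cg$p_value >= alpha, na.rm = TRUE)) {
      return(structure(
        list(selected = colnames(filters$vectors)[selected], fit = fit,
             nonspatial_fit = fit0, correlogram = cg, status = "clean"),
        class = "filter_selection"
      ))
    }
  }
  warning("candidate filters exhausted without removing residual autocorrelation")
  structure(
    list(selected = colnames(filters$vectors)[selected], fit = fit,
         nonspatial_fit = fit0, correlogram = cg, status = "exhausted"),
    class = "filter_selection"
  )
}

#' @export
print.filter_selection <- function(x, ...) {
  cat(sprintf("Spatial filter selection: %d filter(s) selected (%s)\n",
              length(x$selected), x$status))
  cat(sprintf("  pseudo R2: %.3f (nonspatial) -> %.3f (spatial)\n",
              x$nonspatial_fit$pseudo_r2, x$fit$pseudo_r2))
  invisible(x)
}
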
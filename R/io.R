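#' Read and validate occurrence records
#'
#' Reads a delimited occurrence table (header: `species_id`, `locality_id`,
#' `x_km`, `y_km`, `accuracy_km`, `in_study_area`), drops records whose
#' positional accuracy is worse than `accuracy_max_km` (the bound is
#' inclusive: accuracy equal to the threshold is kept), collapses duplicated
#' `(species_id, locality_id)` rows with a warning, and reports parse
#' problems with line numbers. A rejection log is attached as an attribute.
#'
#' @param path path to a delimited text file.
#' @param accuracy_max_km maximum tolerated positional accuracy in km
#'   (default 6). `Inf` disables the filter.
#' @param sep field separator (default comma).
#' @return validated records data.frame with attribute `rejection_log`
#'   (list: `n_input`, `n_kept`, `n_dropped_accuracy`, `n_duplicates`).
#' @export
read_occurrences <- function(path, accuracy_max_km = 6, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("species_id", "locality_id", "x_km", "y_km", "accuracy_km",
            "in_study_area")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("x_km", "y_km", "accuracy_km")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite `%s` at data line(s) %s",
                   col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (any(raw$accuracy_km < 0)) {
    stop("negative positional accuracy at data line(s) ",
         paste(utils::head(which(raw$accuracy_km < 0), 5), collapse = ", "),
         call. = FALSE)
  }
  raw$in_study_area <- as.logical(raw$in_study_area)
  if (anyNA(raw$in_study_area)) {
    stop("`in_study_area` must be logical (TRUE/FALSE)", call. = FALSE)
  }
  n_input <- nrow(raw)
  dup <- duplicated(raw[, c("species_id", "locality_id")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated (species_id, locality_id) row(s)",
                    sum(dup)))
    raw <- raw[!dup, , drop = FALSE]
  }
  keep <- raw$accuracy_km <= accuracy_max_km
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejection_log") <- list(
    n_input = n_input,
    n_kept = nrow(out),
    n_dropped_accuracy = sum(!keep),
    n_duplicates = sum(dup)
  )
  out
}

#' Write occurrence records
#'
#' @param records occurrence data.frame.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles (and validates) the settings of the full analysis with
#' conventional defaults: 20-km cells, 6-km accuracy filter, 10,000
#' randomizations for tie-median, null model and Moran permutations, 14
#' distance classes, 59-km truncation. Reduce the replicate counts for
#' exploratory runs.
#'
#' @param cell_size_km grid cell size (km).
#' @param accuracy_max_km positional accuracy filter (km, inclusive).
#' @param class_thresholds the four richness-class fractions.
#' @param tie_rule quartile tie rule ([assign_quartiles()]).
#' @param R_median,R_null tie-randomization / null-model replicates.
#' @param R_perm Moran permutation count.
#' @param cells tau-b cell policy ([stepwise_curve()]).
#' @param ties tie-randomization policy ([addition_order()]).
#' @param n_classes correlogram distance classes.
#' @param truncation_km PCNM truncation distance (km).
#' @param alpha significance level for filter selection.
#' @param max_filters cap on selected spatial filters per model.
#' @param seed master seed; every randomized stage draws its own child seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_size_km = 20,
                            accuracy_max_km = 6,
                            class_thresholds = c(0.85, 0.60, 0.40, 0.20),
                            tie_rule = "majority",
                            R_median = 10000,
                            R_null = 10000,
                            R_perm = 10000,
                            cells = "all",
                            ties = "all",
                            n_classes = 14,
                            truncation_km = 59,
                            alpha = 0.05,
                            max_filters = 10L,
                            seed = 1L) {
  cfg <- list(
    cell_size_km = cell_size_km, accuracy_max_km = accuracy_max_km,
    class_thresholds = class_thresholds, tie_rule = tie_rule,
    R_median = R_median, R_null = R_null, R_perm = R_perm,
    cells = cells, ties = ties, n_classes = n_classes,
    truncation_km = truncation_km, alpha = alpha,
    max_filters = as.integer(max_filters), seed = as.integer(seed)
  )
  stopifnot(cfg$cell_size_km > 0, cfg$R_median >= 1, cfg$R_null >= 1,
            cfg$n_classes >= 2, cfg$truncation_km > 0,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML key/value file whose keys mirror the arguments of
#' [pipeline_config()]; unset keys take the defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full rare-vs-common analysis pipeline
#'
#' Orchestrates the stages in order: accuracy filtering, per-species range
#' metrics and rarity quartiles, grid richness surface with class mapping,
#' stepwise reconstruction with null model, rare/common richness GLMs with
#' Moran diagnostics and spatial-filter models, and species-rich-cell
#' composition. When `out_dir` is given, every result table is written as
#' CSV together with a JSON run manifest (seeds, settings, config hash).
#' Identical records + config give identical outputs.
#'
#' @param records occurrence data.frame (already read/validated), or a path
#'   accepted by [read_occurrences()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class `srp_pipeline` with elements `profiles`, `summary`
#'   (rsfd), `surface`, `classification`, `reconstruction`, `glm` (list of
#'   fitted models and correlograms), `composition`, `config`,
#'   `rejection_log`.
#' @export
run_pipeline <- function(records, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rejection_log <- NULL
  if (is.character(records)) {
    records <- read_occurrences(records, config$accuracy_max_km)
    rejection_log <- attr(records, "rejection_log")
  } else if (is.finite(config$accuracy_max_km) &&
             "accuracy_km" %in% names(records)) {
    keep <- records$accuracy_km <= config$accuracy_max_km
    rejection_log <- list(n_input = nrow(records), n_kept = sum(keep),
                          n_dropped_accuracy = sum(!keep), n_duplicates = 0L)
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records left after filtering", call. = FALSE)
  seeds <- derive_seeds(config$seed, 4L)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  grid <- run_stage("grid", make_grid(records, config$cell_size_km))
  profiles <- run_stage("range_metrics", {
    p <- species_profiles(records, grid)
    assign_quartiles(p, config$tie_rule)
  })
  summary <- run_stage("range_metrics", rsfd_summary(profiles))
  surface <- run_stage("grid_richness", richness_surface(records, grid))
  classification <- run_stage(
    "grid_richness", classify_richness(surface, config$class_thresholds)
  )
  incidence <- incidence_matrix(surface)
  mle <- stats::setNames(profiles$mle_km, profiles$species_id)[rownames(incidence)]
  recon <- run_stage("reconstruction", reconstruct_srp(
    incidence, mle, R_median = config$R_median, R_null = config$R_null,
    seed = seeds[1], ties = config$ties, cells = config$cells
  ))

  glms <- run_stage("spatial_glm", {
    qmap <- stats::setNames(profiles$rarity_quartile, profiles$species_id)
    q_of <- qmap[rownames(incidence)]
    y <- as.integer(colSums(incidence))
    rare_x <- colSums(incidence[q_of == 1L, , drop = FALSE])
    common_x <- colSums(incidence[q_of == 4L, , drop = FALSE])
    coords <- as.matrix(surface$cells[, c("center_x_km", "center_y_km")])
    filters <- pcnm_filters(coords, config$truncation_km)
    fit_one <- function(xv, fam, sd_) {
      nonspatial <- fit_glm(y, data.frame(predictor = xv), fam)
      spatial <- select_filters(
        y, data.frame(predictor = xv), filters, coords, fam,
        alpha = config$alpha, n_classes = config$n_classes,
        R_perm = config$R_perm, seed = sd_, max_filters = config$max_filters
      )
      list(nonspatial = nonspatial, spatial = spatial)
    }
    list(
      rare = fit_one(rare_x, "negative_binomial", seeds[2]),
      common = fit_one(common_x, "poisson", seeds[3]),
      filters = filters
    )
  })

  composition <- run_stage("composition",
                           src_composition(classification, profiles))

  result <- structure(
    list(profiles = profiles, summary = summary, surface = surface,
         classification = classification, reconstruction = recon,
         glm = glms, composition = composition, config = config,
         rejection_log = rejection_log),
    class = "srp_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.srp_pipeline <- function(x, ...) {
  cat("Rare-vs-common species richness pipeline\n")
  cat(sprintf("  %d species over %d occupied cells (r_max = %d)\n",
              nrow(x$profiles), nrow(x$surface$cells), x$surface$r_max))
  print(x$reconstruction)
  cat(sprintf("  GLM pseudo R2: common %.2f, rare %.2f (nonspatial)\n",
              x$glm$common$nonspatial$pseudo_r2, x$glm$rare$nonspatial$pseudo_r2))
  invisible(x)
}

#' Write all pipeline result tables
#'
#' Writes species profiles, classified surface, reconstruction curves
#' (direction, k, pct_species, pct_ci, tau_b, null envelope, empirical p),
#' the Table-2-style model report, residual correlograms, SRC composition,
#' and a JSON run manifest with seeds and a config hash.
#'
#' @param result an [run_pipeline()] result.
#' @param out_dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "srp_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  put(result$profiles, "species_profiles.csv")
  put(result$classification$cells, "richness_classification.csv")
  curves <- do.call(rbind, lapply(c("ascending", "descending"), function(d) {
    cv <- result$reconstruction[[d]]
    cbind(direction = d, as.data.frame(cv))
  }))
  put(curves, "reconstruction_curves.csv")
  glm_report <- do.call(rbind, lapply(c("rare", "common"), function(pred) {
    m <- result$glm[[pred]]
    data.frame(
      predictor = pred,
      family = m$nonspatial$family,
      model = c("nonspatial", "spatial"),
      n_filters = c(0L, length(m$spatial$selected)),
      pseudo_r2 = c(m$nonspatial$pseudo_r2, m$spatial$fit$pseudo_r2),
      aicc = c(m$nonspatial$aicc, m$spatial$fit$aicc),
      slope = c(m$nonspatial$coefficients[["predictor"]],
                m$spatial$fit$coefficients[["predictor"]])
    )
  }))
  put(glm_report, "glm_models.csv")
  coef_tab <- do.call(rbind, lapply(c("rare", "common"), function(pred) {
    m <- result$glm[[pred]]
    one <- function(fit, model) {
      est <- stats::coef(fit$fit)
      se <- sqrt(diag(stats::vcov(fit$fit)))
      data.frame(predictor = pred, model = model, term = names(est),
                 estimate = unname(est), std_error = unname(se))
    }
    rbind(one(m$nonspatial, "nonspatial"), one(m$spatial$fit, "spatial"))
  }))
  put(coef_tab, "glm_coefficients.csv")
  for (pred in c("rare", "common")) {
    put(as.data.frame(result$glm[[pred]]$spatial$correlogram),
        sprintf("correlogram_%s.csv", pred))
  }
  put(result$composition$per_cell, "src_composition_cells.csv")
  put(result$composition$summary, "src_composition_summary.csv")

  cfg <- unclass(result$config)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "srpdrivers",
    version = as.character(utils::packageVersion("srpdrivers")),
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    n_species = nrow(result$profiles),
    n_cells = nrow(result$surface$cells),
    files = basename(paths)
  )
  unlink(tmp)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
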
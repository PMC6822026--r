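# small in-code fixtures shared across tests

make_records <- function(species_id, x_km, y_km,
                         locality_id = sprintf("L%03d", seq_along(x_km)),
                         accuracy_km = 0,
                         in_study_area = TRUE) {
  data.frame(
    species_id = species_id,
    locality_id = locality_id,
    x_km = x_km,
    y_km = y_km,
    accuracy_km = accuracy_km,
    in_study_area = in_study_area,
    stringsAsFactors = FALSE
  )
}

# independent pair-classification oracle for Kendall tau-b:
# classify every pair as concordant / discordant / tied in x / tied in y and
# use tau_b = (C - D) / sqrt((C + D + Tx)(C + D + Ty))
tau_b_oracle <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[1, ]] - x[ij[2, ]]
  dy <- y[ij[1, ]] - y[ij[2, ]]
  C <- sum(dx * dy > 0)
  D <- sum(dx * dy < 0)
  Tx <- sum(dx == 0 & dy != 0)
  Ty <- sum(dy == 0 & dx != 0)
  if (C + D + Tx == 0 || C + D + Ty == 0) return(NA_real_)
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# brute-force per-cell species sets from records
richness_oracle <- function(records, grid) {
  keep <- records$in_study_area
  res <- list()
  for (i in which(keep)) {
    cx <- floor((records$x_km[i] - grid$origin_x_km) / grid$cell_size_km) + 1
    cy <- floor((records$y_km[i] - grid$origin_y_km) / grid$cell_size_km) + 1
    if (cx < 1 || cx > grid$n_cols || cy < 1 || cy > grid$n_rows) next
    id <- sprintf("c%d_%d", cx, cy)
    res[[id]] <- union(res[[id]], records$species_id[i])
  }
  res
}

# a small assemblage with its derived objects, used by several files
toy_assemblage <- function(n_species = 40, scenario = "neutral", seed = 11,
                           region = c(300, 200)) {
  cfg <- scenario_config(
    n_species = n_species,
    region_width_km = region[1], region_height_km = region[2],
    scenario = scenario, seed = seed
  )
  rec <- generate_assemblage(cfg)
  grid <- make_grid(rec)
  surface <- richness_surface(rec, grid)
  list(config = cfg, records = rec, grid = grid, surface = surface,
       incidence = incidence_matrix(surface),
       profiles = species_profiles(rec))
}
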
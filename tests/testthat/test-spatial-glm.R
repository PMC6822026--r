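test_that("poisson GLM: closed-form intercept and parameter recovery", {
  y <- c(2L, 5L, 1L, 7L, 3L, 0L, 4L)
  fit0 <- fit_glm(y, NULL, "poisson")
  expect_equal(unname(fit0$coefficients), log(mean(y)))
  expect_equal(fit0$pseudo_r2, 0)
  expect_error(fit_glm(c(-1, 2, 3)), "nonnegative")

  set.seed(314)
  n <- 2000
  x <- rnorm(n)
  y2 <- rpois(n, exp(0.5 + 0.3 * x))
  fit <- fit_glm(y2, data.frame(x = x), "poisson")
  se <- sqrt(diag(vcov(fit$fit)))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0.5), 3 * se[1])
  expect_lt(abs(fit$coefficients[["x"]] - 0.3), 3 * se[2])
})

test_that("negative binomial nests Poisson and wins on overdispersed counts", {
  set.seed(99)
  n <- 400
  x <- rnorm(n)
  # Poisson data: NB theta should blow up (dispersion ~ 1)
  y_pois <- rpois(n, exp(1 + 0.4 * x))
  nb_on_pois <- suppressWarnings(fit_glm(y_pois, data.frame(x = x),
                                         "negative_binomial"))
  expect_gt(nb_on_pois$theta, 20)
  # overdispersed (gamma-mixed) data: NB beats Poisson by AICc
  y_od <- rpois(n, rgamma(n, shape = 1.2, rate = 1.2 / exp(1 + 0.4 * x)))
  f_p <- fit_glm(y_od, data.frame(x = x), "poisson")
  f_nb <- fit_glm(y_od, data.frame(x = x), "negative_binomial")
  expect_lt(f_nb$aicc, f_p$aicc)
  expect_equal(f_nb$n_params, 3L) # intercept + slope + theta
})

test_that("pseudo R-squared is explained deviance and invariant to rescaling", {
  set.seed(17)
  x <- rnorm(80)
  y <- rpois(80, exp(0.8 + 0.5 * x))
  fit <- fit_glm(y, data.frame(x = x), "poisson")
  expect_equal(fit$pseudo_r2,
               (fit$null_deviance - fit$residual_deviance) / fit$null_deviance)
  # independent recomputation of both deviances from the Poisson likelihood
  dev_pois <- function(y, mu) {
    2 * sum(ifelse(y == 0, 0, y * log(y / mu)) - (y - mu))
  }
  expect_equal(fit$residual_deviance, dev_pois(y, fit$fitted), tolerance = 1e-6)
  expect_equal(fit$null_deviance, dev_pois(y, rep(mean(y), 80)), tolerance = 1e-6)
  # rescaling the predictor changes nothing
  fit2 <- fit_glm(y, data.frame(x = x * 1000), "poisson")
  expect_equal(fit2$pseudo_r2, fit$pseudo_r2, tolerance = 1e-8)
  # saturated fit explains everything
  f <- factor(seq_along(y))
  fit_sat <- suppressWarnings(fit_glm(y, data.frame(f = f), "poisson"))
  expect_equal(fit_sat$pseudo_r2, 1, tolerance = 1e-6)
  # constant response is flagged
  expect_warning(r2c <- pseudo_r2(suppressWarnings(fit_glm(rep(3L, 20), NULL))),
                 "constant")
  expect_true(is.na(r2c))
})

test_that("AICc matches the plug-in formula and tends to AIC for large n", {
  fake <- list(log_likelihood = -100, n_params = 2L, n = 50L)
  expect_equal(aicc(fake), 204 + 12 / 47)
  expect_equal(aicc(fake, n = 1e9), 204, tolerance = 1e-6)
  expect_error(aicc(list(log_likelihood = -10, n_params = 5L, n = 6L)), "n > k")
})

test_that("Moran's I: null expectation, gradient detection, and class structure", {
  set.seed(60)
  coords <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  # mean I over independent simulations approaches -1/(n-1), in every class
  sims <- replicate(600, {
    cg <- morans_i_correlogram(rnorm(25), coords, n_classes = 4, R = 0)
    cg$I
  })
  expect_lt(max(abs(rowMeans(sims) - (-1 / 24))), 0.05)

  # smooth gradient: strong positive I at short range, negative at long range
  gx <- expand.grid(x = seq(0, 140, by = 20), y = seq(0, 100, by = 20))
  vals <- gx$x + gx$y + rnorm(nrow(gx), 0, 5)
  cg <- morans_i_correlogram(vals, as.matrix(gx), n_classes = 6, R = 400,
                             seed = 2)
  expect_gt(cg$I[1], 0.3)
  expect_lt(cg$p_value[1], 0.05)
  expect_lt(cg$I[6], 0)
  # every pair lands in exactly one class
  expect_equal(sum(cg$n_pairs), choose(nrow(gx), 2))
  expect_equal(unique(cg$expected_I), -1 / (nrow(gx) - 1))
  # continuous coordinates (no tied distances): counts equal up to +/-1
  cg2 <- morans_i_correlogram(rnorm(25), coords, n_classes = 5, R = 0)
  expect_lte(diff(range(cg2$n_pairs)), 1)
  expect_equal(sum(cg2$n_pairs), choose(25, 2))

  expect_error(morans_i_correlogram(rep(1, 25), coords), "constant")
  expect_error(morans_i_correlogram(rnorm(5), coords[1:5, ]), "at least 10")
})

test_that("Moran's I agrees with ape on a single all-pairs class", {
  skip_if_not_installed("ape")
  set.seed(4)
  coords <- cbind(runif(20, 0, 50), runif(20, 0, 50))
  vals <- rnorm(20)
  cg <- morans_i_correlogram(vals, coords, n_classes = 1, R = 0)
  w <- matrix(1, 20, 20) # all pairs connected
  diag(w) <- 0
  # ape's analytic variance degenerates for all-ones weights (harmless here:
  # only the observed statistic is compared)
  ape_obs <- suppressWarnings(ape::Moran.I(vals, w)$observed)
  expect_equal(cg$I, ape_obs, tolerance = 1e-10)
})

test_that("PCNM filters: spectral properties and decomposition oracle", {
  set.seed(12)
  coords <- cbind(runif(30, 0, 200), runif(30, 0, 150))
  fl <- pcnm_filters(coords, truncation_km = 59)
  v <- fl$vectors
  # mutual orthogonality
  gram <- crossprod(v)
  expect_lt(max(abs(gram - diag(ncol(v)))), 1e-8)
  # translation invariance
  fl2 <- pcnm_filters(coords + 1000, truncation_km = 59)
  expect_equal(abs(diag(cor(fl$vectors, fl2$vectors))), rep(1, ncol(v)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fl$values, fl2$values)
  # eigen-reconstruction of the centered matrix (all eigenvalues, so rebuild
  # from the full decomposition: positive part must reproduce the positive
  # subspace projection)
  proj <- v %*% diag(fl$values, ncol(v)) %*% t(v)
  eig_full <- eigen(fl$centered, symmetric = TRUE)
  pos <- eig_full$values > max(abs(eig_full$values)) * 1e-10
  proj_oracle <- eig_full$vectors[, pos] %*% diag(eig_full$values[pos]) %*%
    t(eig_full$vectors[, pos])
  expect_lt(max(abs(proj - proj_oracle)), 1e-8)
  expect_error(pcnm_filters(coords[c(1, 1, 1), ]), "coincide")
})

test_that("PCNM filters span the same space as vegan's", {
  skip_if_not_installed("vegan")
  set.seed(13)
  coords <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  fl <- pcnm_filters(coords, truncation_km = 40)
  vp <- vegan::pcnm(dist(coords), threshold = 40)
  expect_equal(ncol(fl$vectors), ncol(vp$vectors))
  expect_equal(fl$values, vp$values[vp$values > 1e-8 * max(vp$values)],
               tolerance = 1e-6)
  # same eigenvectors up to sign
  cors <- abs(diag(cor(fl$vectors, vp$vectors)))
  expect_equal(cors, rep(1, ncol(fl$vectors)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("on common-driven assemblages the common-species GLM outpredicts the rare-species GLM", {
  cfg <- scenario_config(n_species = 150, scenario = "common_driven", seed = 1)
  rec <- generate_assemblage(cfg)
  rec <- rec[rec$accuracy_km <= 6, ]
  g <- make_grid(rec)
  prof <- assign_quartiles(species_profiles(rec, g))
  s <- richness_surface(rec, g)
  inc <- incidence_matrix(s)
  q_of <- setNames(prof$rarity_quartile, prof$species_id)[rownames(inc)]
  y <- as.integer(colSums(inc))
  rare <- suppressWarnings(
    fit_glm(y, data.frame(p = colSums(inc[q_of == 1L, , drop = FALSE])),
            "negative_binomial"))
  common <- suppressWarnings(
    fit_glm(y, data.frame(p = colSums(inc[q_of == 4L, , drop = FALSE])),
            "poisson"))
  expect_gt(common$pseudo_r2, rare$pseudo_r2)
  expect_lt(common$aicc, rare$aicc)
})

test_that("filter selection recovers planted spatial structure and keeps the focal slope", {
  gxy <- as.matrix(expand.grid(x = seq(10, 130, by = 20),
                               y = seq(10, 130, by = 20)))
  fl <- pcnm_filters(gxy, truncation_km = 59)
  set.seed(1)
  x <- rnorm(nrow(gxy))
  # no spatial structure: nothing should be selected
  y0 <- rpois(nrow(gxy), exp(1 + 0.3 * x))
  sel0 <- select_filters(y0, data.frame(predictor = x), fl, gxy,
                         family = "poisson", n_classes = 5, R_perm = 200,
                         seed = 3)
  expect_equal(length(sel0$selected), 0L)
  expect_equal(sel0$status, "none_needed")

  # plant a strong broad-scale filter signal
  y1 <- rpois(nrow(gxy), exp(1 + 0.3 * x + 2.5 * fl$vectors[, 1]))
  sel1 <- select_filters(y1, data.frame(predictor = x), fl, gxy,
                         family = "poisson", n_classes = 5, R_perm = 200,
                         seed = 4)
  expect_true("filter_1" %in% sel1$selected)
  expect_true(all(sel1$correlogram$p_value >= 0.05))
  # spatial model explains at least as much deviance as the nonspatial one
  expect_gte(sel1$fit$pseudo_r2, sel1$nonspatial_fit$pseudo_r2)
  # focal coefficient moves by less than one nonspatial standard error
  se_x <- sqrt(diag(vcov(sel1$nonspatial_fit$fit)))[["predictor"]]
  shift <- abs(sel1$fit$coefficients[["predictor"]] -
               sel1$nonspatial_fit$coefficients[["predictor"]])
  expect_lt(shift, se_x)
})
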
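test_that("seasonal inputs aggregate fields per rule, keeping classes
           fractional", {
  env <- flat_env(sst_summer = 28, sst_winter = 24, sss_class = 5)
  env$sss_class_winter <- rep(6L, nrow(env))
  env <- env_stack(env)
  expect_equal(unique(seasonal_input(env, "sst", "mean_of_seasons")), 26)
  expect_equal(unique(seasonal_input(env, "sst", "warm_season")), 28)
  expect_equal(unique(seasonal_input(env, "sst", "cool_season")), 24)
  expect_equal(unique(seasonal_input(env, "sss_class", "mean_of_seasons")),
               5.5)
})

test_that("susceptibility reproduces hand-evaluated published cases", {
  params <- default_factory_params()
  # tropical reef cell
  env <- flat_env(sst_summer = 28, sst_winter = 24, sss_class = 5,
                  prod = 0.015, depth = 20)
  f <- susceptibility(env, params$photozoan_T)
  expected <- 0.03 + 0.64 * fuzzy_gaussian(26, 25.7, 0.03) + 0.06 + 0.27
  expect_equal(unique(f$susceptibility), expected, tolerance = 1e-12)
  expect_equal(unique(f$susceptibility), 0.998, tolerance = 1e-3)

  # hypersaline gulf cell
  env_b <- flat_env(sst_summer = 33, sst_winter = 20, sss_class = 8,
                    prod = 0.02, depth = 20)
  f_b <- susceptibility(env_b, params$biochemical)
  expected_b <- 0.10 + 0.45 * fuzzy_sigmoid_large(33, 30.5, 58) + 0.45 * 1
  expect_equal(unique(f_b$susceptibility), expected_b, tolerance = 1e-12)
  expect_equal(unique(f_b$susceptibility), 0.995, tolerance = 1e-3)

  # warm-temperate cell: production x persistence seasonality product
  env_c <- flat_env(sst_summer = 25, sst_winter = 12, sss_class = 7,
                    prod = 0.0203, depth = 50)
  f_c <- susceptibility(env_c, params$photo_C)
  expected_c <- 0.04 +
    0.62 * fuzzy_gaussian(25, 25.25, 0.025) *
      fuzzy_gaussian(12, 12.325, 0.0244) +
    0.12 + 0.22
  expect_equal(unique(f_c$susceptibility), expected_c, tolerance = 1e-12)

  # high terrigenous inhibits every factory
  env_t <- flat_env(terr = "high")
  for (p in params) {
    expect_true(all(is.na(susceptibility(env_t, p)$susceptibility)))
  }
})

test_that("occurrence uses a strict threshold", {
  env <- flat_env()
  susc <- susceptibility(env, default_factory_params()$photozoan_T)
  expect_true(all(occurrence(susc, 0.7)$present))
  expect_false(any(occurrence(susc, unique(susc$susceptibility))$present))
  masked <- susc
  masked$susceptibility[1] <- NA
  expect_false(occurrence(masked, 0.1)$present[1])
})

test_that("a temperate cell with year-round SST between 18 and 24 degC stays
           below the photozoan-T threshold", {
  # mean SST 21 degC with every other membership at 1: the published
  # southwest-Australia exclusion
  env <- flat_env(sst_summer = 21, sst_winter = 21)
  params <- sst_only_params()
  f <- susceptibility(env, params$photozoan_T)
  expected <- 0.03 + 0.64 * fuzzy_gaussian(21, 25.7, 0.03) + 0.06 + 0.27
  expect_equal(unique(f$susceptibility), expected, tolerance = 1e-12)
  expect_lt(unique(f$susceptibility), 0.7)
  expect_equal(unique(f$susceptibility), 0.69, tolerance = 0.01)
})

test_that("competing factories resolve by susceptibility margin with fixed
           tie order, and the background factory needs its productivity
           floor", {
  env <- flat_env(nlat = 2, nlon = 2)
  params <- default_factory_params()
  mk_susc <- function(f, vals) {
    structure(tibble::tibble(lat = env$lat, lon = env$lon,
                             susceptibility = vals),
              factory = f, threshold = params[[f]]$threshold,
              class = c("susceptibility_map", class(tibble::tibble())))
  }
  # cell 1: biochemical margin 0.35 beats photozoan margin 0.28
  # cell 2: only photozoan present; cell 3: nobody -> background
  # cell 4: nobody and productivity below floor -> none
  env$prod_summer <- c(0.02, 0.02, 0.06, 0.004)
  env$prod_winter <- c(0.02, 0.02, 0.06, 0.004)
  env <- env_stack(env)
  suscs <- list(
    biochemical = mk_susc("biochemical", c(0.95, 0.1, 0.1, 0.1)),
    photozoan_T = mk_susc("photozoan_T", c(0.98, 0.9, 0.1, 0.1)),
    photo_C = mk_susc("photo_C", c(0.2, 0.2, 0.2, 0.2)),
    heterozoan_C = mk_susc("heterozoan_C", c(0.9, 0.9, 0.9, 0.9))
  )
  map <- combine_factories(suscs, params, env)
  expect_identical(map$factory,
                   c("biochemical", "photozoan_T", "heterozoan_C", "none"))

  # exact margin tie: fixed priority order wins
  suscs$biochemical$susceptibility <- c(0.90, 0.1, 0.1, 0.1)   # margin 0.30
  suscs$photozoan_T$susceptibility <- c(1.00, 0.9, 0.1, 0.1)   # margin 0.30
  map_tie <- combine_factories(suscs, params, env)
  expect_identical(map_tie$factory[1], "biochemical")
})

test_that("the combined assignment is a partition even where raw presence
           regions overlap in temperature space", {
  # dense (summer, winter) sweep with salinity/productivity neutralized
  s <- seq(16, 36, by = 0.25)
  w <- seq(4, 32, by = 0.25)
  grid <- tidyr::expand_grid(sst_summer = s, sst_winter = w) |>
    dplyr::filter(sst_summer >= sst_winter)
  nlat <- 107
  nlon <- ceiling(nrow(grid) / nlat)
  pad <- nlat * nlon - nrow(grid)
  env <- tibble::tibble(
    lat = rep(seq(0.5, by = 1, length.out = nlat), times = nlon),
    lon = rep(seq(0.5, by = 1, length.out = nlon), each = nlat),
    sst_summer = c(grid$sst_summer, rep(20, pad)),
    sst_winter = c(grid$sst_winter, rep(10, pad)),
    sss_class_summer = 5L, sss_class_winter = 5L,
    prod_summer = 0.02, prod_winter = 0.02,
    bathymetry = 20, terrigenous = "none") |>
    env_stack()
  params <- sst_only_params()
  pred <- predict_factories(env, params)
  wide <- tidyr::pivot_wider(pred$susceptibility,
                             id_cols = c("lat", "lon"),
                             names_from = "factory",
                             values_from = "present")
  # raw presence regions of the three temperature-defined factories overlap
  # in a warm transition band ...
  expect_gt(sum(wide$biochemical & wide$photozoan_T), 0)
  # ... but the combination assigns exactly one factory per cell
  expect_true(all(!is.na(pred$map$factory)))
  n_claims <- wide$biochemical + wide$photozoan_T + wide$photo_C
  assigned_one <- pred$map$factory %in%
    c("biochemical", "photozoan_T", "photo_C")
  expect_true(all(assigned_one[n_claims >= 1]))
  # each factory keeps its core temperature domain
  core <- function(ss, ww) {
    i <- which(abs(env$sst_summer - ss) < 0.13 &
                 abs(env$sst_winter - ww) < 0.13)[1]
    pred$map$factory[i]
  }
  expect_identical(core(33, 20), "biochemical")
  expect_identical(core(27, 25), "photozoan_T")
  expect_identical(core(25, 11), "photo_C")
})

test_that("susceptibility stays on [0,1] for random valid parameterizations
           and is monotone under membership improvement", {
  w <- tiny_world()
  set.seed(123)
  random_spec <- function() {
    form <- sample(c("gaussian", "near_gaussian", "independent"), 1)
    if (form == "independent") return(membership_spec("independent"))
    membership_spec(form, runif(1, -5, 35), 10^runif(1, -3, 2))
  }
  for (i in 1:25) {
    raw <- runif(4)
    wt <- raw / sum(raw)
    p <- factory_params(
      "random", sst = random_spec(), sss = random_spec(),
      prod = random_spec(),
      weights = c(z = wt[1], sst = wt[2], sss = wt[3], prod = wt[4]),
      threshold = runif(1, 0.05, 0.95), depth_max = sample(c(100, 200), 1))
    f <- susceptibility(w$env, p)$susceptibility
    expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  }

  # moving SST toward the optimum cannot decrease F
  params <- default_factory_params()
  env_far <- flat_env(sst_summer = 23, sst_winter = 19)
  env_near <- flat_env(sst_summer = 26.7, sst_winter = 24.7)
  f_far <- susceptibility(env_far, params$photozoan_T)$susceptibility
  f_near <- susceptibility(env_near, params$photozoan_T)$susceptibility
  expect_true(all(f_near >= f_far))
})

test_that("prediction is self-consistent, empty on land, and flips with the
           latitude axis", {
  w <- tiny_world()
  truth <- tiny_truth()
  pred <- predict_factories(w$env, masks = w$masks)
  expect_identical(pred$map$factory, truth$factory)

  land <- flat_env(depth = -100)
  land$sst_summer <- NA_real_
  land$sst_winter <- NA_real_
  land$prod_summer <- NA_real_
  land$prod_winter <- NA_real_
  land$sss_class_summer <- NA_integer_
  land$sss_class_winter <- NA_integer_
  land$terrigenous <- NA_character_
  pred_land <- predict_factories(env_stack(land))
  expect_true(all(is.na(pred_land$map$factory)))

  flipped_env <- w$env
  flipped_env$lat <- -flipped_env$lat
  flipped_env <- env_stack(flipped_env)
  pred_flip <- predict_factories(flipped_env)
  merged <- dplyr::inner_join(
    pred$map, dplyr::mutate(pred_flip$map, lat = -lat),
    by = c("lat", "lon"), suffix = c("", "_flip"))
  expect_identical(merged$factory, merged$factory_flip)
})

test_that("uniform warming shifts the tropical reef belt poleward", {
  w <- tiny_world()
  warm_env <- w$env
  warm_env$sst_summer <- pmin(warm_env$sst_summer + 5, 36)
  warm_env$sst_winter <- pmin(warm_env$sst_winter + 5, warm_env$sst_summer)
  warm_env <- env_stack(warm_env)
  base_lat <- dplyr::filter(predict_factories(w$env)$map,
                            factory == "photozoan_T")$lat
  warm_lat <- dplyr::filter(predict_factories(warm_env)$map,
                            factory == "photozoan_T")$lat
  expect_gt(max(abs(warm_lat)), max(abs(base_lat)))
})

test_that("factory parameterizations round-trip through YAML and tidy
           accessors summarize predictions", {
  params <- default_factory_params()
  f <- tempfile(fileext = ".yaml")
  write_factory_params(params, f)
  back <- read_factory_params(f)
  expect_identical(names(back), names(params))
  for (nm in names(params)) {
    expect_equal(back[[nm]]$weights, params[[nm]]$weights)
    expect_equal(back[[nm]]$threshold, params[[nm]]$threshold)
    expect_identical(back[[nm]]$sst_rule, params[[nm]]$sst_rule)
  }
  expect_equal(back$photo_C$sst$persistence$midpoint, 12.325)
  expect_true(back$heterozoan_C$background)
  unlink(f)

  pred <- predict_factories(tiny_world()$env)
  g <- glance(pred)
  expect_setequal(g$factory, names(params))
  expect_true(all(g$cells_assigned <= g$cells_present))
  td <- tidy(pred)
  expect_true(all(td$susceptibility >= 0 & td$susceptibility <= 1,
                  na.rm = TRUE))
})
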
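test_that("island generation is deterministic and rejects bad inputs", {
  a <- generate_island(c(32, 40), seed = 7)
  b <- generate_island(c(32, 40), seed = 7)
  expect_identical(a, b)
  c2 <- generate_island(c(32, 40), seed = 8)
  expect_false(identical(a$elevation$values, c2$elevation$values))

  expect_error(generate_island(c(16, 64)), "grid_size")
  expect_error(generate_island(c(64, 64),
                               climate_params = list(lapse_rate = -0.001)),
               "lapse_rate")
})

test_that("zero lapse rate and zero noise give spatially constant temperature", {
  ls <- generate_island(c(32, 32), seed = 2,
                        climate_params = list(lapse_rate = 0,
                                              t_noise_sd = 0, p_noise_sd = 0))
  for (m in c(1, 7, 12)) {
    tv <- ls$monthly_t[[m]]$values
    land <- is.finite(tv)
    expect_equal(stats::sd(tv[land]), 0)
    expect_equal(unique(tv[land]), ls$climate_params$sea_level_t[m])
  }
})

test_that("temperature decreases and precipitation increases with elevation", {
  ls <- tiny_landscape()
  elev <- as.vector(ls$elevation$values)
  jul <- as.vector(ls$monthly_t[[7]]$values)
  land <- is.finite(elev)
  # summit vs coast, per the lapse formula
  summit <- which.max(ls$elevation$values)
  coast <- which(land & elev < 50)[1]
  expect_lt(jul[summit], jul[coast])
  expect_lt(stats::cor(jul[land], elev[land]), 0)
  pj <- as.vector(ls$monthly_p[[7]]$values)
  expect_gt(stats::cor(pj[land], elev[land]), 0)
  # elevation non-negative on land, nodata on sea shared by all grids
  expect_true(all(elev[land] >= 0))
  for (g in c(ls$monthly_t, ls$monthly_p))
    expect_identical(is.finite(g$values), is.finite(ls$elevation$values))
})

test_that("virtual species truncation respects the containment chain", {
  ls <- tiny_landscape()
  niche <- list(tm = list(opt = 11, sd = 5))
  for (seed in 1:3) {
    tr <- define_virtual_species(ls, niche, truncation_elevation = 1000,
                                 clearing_fraction = 0.95, n_coppices = 10,
                                 seed = seed)
    fund <- tr$fundamental_range$values
    real <- tr$realized_range$values
    expect_true(all(fund[real == 1] == 1, na.rm = TRUE))   # realized subset
    expect_lt(sum(real, na.rm = TRUE), sum(fund, na.rm = TRUE))
    cop <- cbind(tr$coppice_cells$row, tr$coppice_cells$col)
    expect_true(all(fund[cop] == 1))
    expect_true(all(real[cop] == 0))
    # deterministic per seed
    tr2 <- define_virtual_species(ls, niche, truncation_elevation = 1000,
                                  clearing_fraction = 0.95, n_coppices = 10,
                                  seed = seed)
    expect_identical(tr, tr2)
  }
})

test_that("clearing edge cases: none, total, coppice shortfall", {
  ls <- tiny_landscape()
  niche <- list(tm = list(opt = 11, sd = 5))
  tr0 <- define_virtual_species(ls, niche, clearing_fraction = 0,
                                n_coppices = 0, seed = 1)
  expect_identical(tr0$realized_range$values, tr0$fundamental_range$values)
  expect_error(
    define_virtual_species(ls, niche, clearing_fraction = 0, n_coppices = 5,
                           seed = 1),
    "short by")
  # clearing everything below the summit empties the realized range when
  # the niche excludes the summit itself
  tr1 <- define_virtual_species(ls, niche, clearing_fraction = 1,
                                truncation_elevation = max(ls$elevation$values,
                                                           na.rm = TRUE),
                                n_coppices = 0, seed = 1)
  expect_equal(sum(tr1$realized_range$values, na.rm = TRUE), 0)
})

test_that("occurrence sampling: census, containment, seed behaviour", {
  ls <- tiny_landscape()
  tr <- define_virtual_species(ls, list(tm = list(opt = 11, sd = 5)),
                               n_coppices = 5, seed = 2)
  n_occ <- sum(tr$realized_range$values, na.rm = TRUE)

  census <- sample_occurrences(tr, n_occ, detection_prob = 1, seed = 1)
  pres <- census[census$role == "presence", ]
  expect_equal(nrow(pres), n_occ)
  expect_equal(nrow(unique(pres[c("x", "y")])), n_occ)     # each cell once
  expect_equal(sum(census$role == "coppice"), 5)

  expect_error(sample_occurrences(tr, n_occ + 1, seed = 1), "exceeds")

  s1 <- sample_occurrences(tr, 50, seed = 1)
  s2 <- sample_occurrences(tr, 50, seed = 2)
  expect_equal(sum(s1$role == "presence"), sum(s2$role == "presence"))
  expect_false(identical(s1$x, s2$x))
  # all presences inside the realized range
  at <- extract_at(tr$realized_range, s1$x[s1$role == "presence"],
                   s1$y[s1$role == "presence"])
  expect_true(all(at == 1))
})

test_that("bird truth is contained in its hosts and reduces to a pure
           climate species without the host requirement", {
  ls <- tiny_landscape()
  niche_p <- list(tm = list(opt = 11, sd = 5))
  niche_b <- list(tm = list(opt = 9, sd = 4))
  pine <- define_virtual_species(ls, niche_p, n_coppices = 5, seed = 2)
  bird <- generate_bird_truth(list(pine), ls, niche_b, seed = 3)
  pr <- pine$realized_range$values
  br <- bird$realized_range$values
  expect_true(all(pr[br == 1] == 1, na.rm = TRUE))
  pf <- pine$fundamental_range$values
  expect_true(all(pf[bird$fundamental_range$values == 1] == 1, na.rm = TRUE))

  # empty host range -> empty bird range
  empty <- pine
  empty$realized_range$values <- ifelse(is.na(pr), NA_real_, 0)
  empty$fundamental_range <- empty$realized_range
  bird0 <- generate_bird_truth(list(empty), ls, niche_b, seed = 3)
  expect_equal(sum(bird0$realized_range$values, na.rm = TRUE), 0)

  # host indicator forced to 1 reproduces an untruncated climate species
  free <- generate_bird_truth(list(pine), ls, niche_b, seed = 3,
                              require_host = FALSE)
  ref <- define_virtual_species(ls, niche_b, clearing_fraction = 0,
                                n_coppices = 0, seed = 3)
  expect_equal(free$fundamental_suitability$values,
               ref$fundamental_suitability$values)
  expect_equal(free$realized_range$values, ref$realized_range$values)
})

test_that("scenario anomalies are coarse, smooth around their means, and
           a null scenario leaves the climate unchanged", {
  ls <- tiny_landscape()
  scen <- generate_scenarios(ls, seed = 5)
  expect_length(scen, 3)
  expect_setequal(vapply(scen, `[[`, "", "id"), c("A1", "A2", "B1"))
  specs <- default_scenarios()
  for (i in seq_along(scen)) {
    mean_dT <- mean(vapply(scen[[i]]$coarse_dT,
                           function(g) mean(g$values), 0))
    expect_lt(abs(mean_dT - specs$dT[i]), 3 * 0.4 / sqrt(12))
  }
  expect_error(generate_scenarios(ls, specs[0, ]), "empty")

  null <- generate_scenarios(ls, data.frame(id = "none", dT = 0, dP = 0),
                             noise_sd_t = 0, noise_sd_p = 0, seed = 5)
  fut <- downscale_anomaly(null[[1]], ls)
  for (m in 1:12) {
    expect_equal(fut$monthly_t[[m]]$values, ls$monthly_t[[m]]$values)
    expect_equal(fut$monthly_p[[m]]$values, ls$monthly_p[[m]]$values)
  }
})
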
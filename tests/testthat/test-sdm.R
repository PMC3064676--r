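test_that("pseudo-absence sampling excludes presences and honours bounds", {
  ls <- generate_island(c(50, 50), seed = 4)
  mask <- ls$elevation
  land <- which(is.finite(mask$values))
  nr <- nrow(mask$values)
  pres_cells <- land[seq(1, length(land), by = 7)]
  ctr <- cell_centers(mask, ((pres_cells - 1) %% nr) + 1,
                      ((pres_cells - 1) %/% nr) + 1)
  pres <- data.frame(x = ctr$x, y = ctr$y, species = "p", role = "presence")
  eligible <- length(land) - length(pres_cells)

  expect_equal(nrow(sample_pseudo_absences(mask, pres, n = 0, n_sets = 1,
                                           seed = 1)[[1]]), 0)
  # exhaustion: every eligible cell exactly once per set
  census <- sample_pseudo_absences(mask, pres, n = eligible, n_sets = 2,
                                   seed = 1)
  for (s in census) {
    expect_equal(nrow(unique(s[c("x", "y")])), eligible)
    # no sampled cell coincides with a presence cell
    expect_equal(nrow(merge(s[c("x", "y")], pres[c("x", "y")])), 0)
  }
  expect_error(sample_pseudo_absences(mask, pres, n = eligible + 1,
                                      n_sets = 1, seed = 1), "short by")

  # sets from one call differ but are reproducible under the seed
  sets <- sample_pseudo_absences(mask, pres, n = 500, n_sets = 2, seed = 3)
  key <- function(d) paste(d$x, d$y)
  expect_lt(length(intersect(key(sets[[1]]), key(sets[[2]]))), 500)
  sets2 <- sample_pseudo_absences(mask, pres, n = 500, n_sets = 2, seed = 3)
  expect_identical(sets, sets2)
})

test_that("training table extraction looks up cells and drops nodata points", {
  v <- matrix(as.numeric(1:16), 4, 4)
  v[1, 1] <- NA
  g1 <- raster_grid(v)
  g2 <- raster_grid(v * 10)
  ctr <- cell_centers(g1, c(2, 3, 1), c(2, 4, 1))
  pres <- data.frame(x = ctr$x[1:2], y = ctr$y[1:2])
  abs_ <- data.frame(x = ctr$x[c(3, 1)], y = ctr$y[c(3, 1)])  # 1 on nodata,
  # 1 absence on the same cell as a presence
  tab <- extract_training_table(list(a = g1, b = g2), pres, abs_)
  expect_equal(nrow(tab), 3)                       # nodata point dropped
  expect_equal(attr(tab, "n_dropped"), 1)
  expect_equal(tab$a, c(v[2, 2], v[3, 4], v[2, 2]))
  expect_equal(tab$b, 10 * tab$a)
  expect_equal(tab$response, c(1, 1, 0))           # shared cell keeps both

  allna <- data.frame(x = ctr$x[3], y = ctr$y[3])
  expect_error(extract_training_table(list(a = g1), allna, allna), "nodata")
})

test_that("AUC equals the all-pairs Mann-Whitney oracle", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auc_bruteforce(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "classes")

  set.seed(101)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    s <- round(stats::runif(n), 2)          # many ties
    l <- stats::rbinom(n, 1, 0.5)
    if (sum(l) == 0 || sum(l) == n) next
    expect_equal(auc(s, l), auc_bruteforce(s, l))
  }
})

test_that("TSS matches hand-counted confusion tables and is invariant
           under monotone score transforms", {
  expect_equal(tss(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5), 1)
  expect_equal(tss(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.05), 0)
  # 10 presences with 8 >= t (sens .8), 10 absences with 7 < t (spec .7)
  scores <- c(seq(0.6, 0.95, length.out = 8), 0.2, 0.3,
              seq(0.05, 0.35, length.out = 7), 0.7, 0.8, 0.9)
  labels <- rep(c(1, 0), c(10, 10))
  expect_equal(tss(scores, labels, 0.5), 0.8 + 0.7 - 1)
  expect_error(tss(1:3, c(0, 0, 0), 0.5), "classes")

  set.seed(55)
  s <- stats::runif(50); l <- stats::rbinom(50, 1, 0.5)
  l[1:2] <- c(0, 1)
  for (t in c(0.2, 0.5, 0.9)) {
    expect_equal(tss(s^2, l, t^2), tss(s, l, t))
    expect_equal(tss(exp(s), l, exp(t)), tss(s, l, t))
  }
})

test_that("every technique is deterministic per seed and learns a
           separable signal", {
  tab <- separable_table(200)
  cfg <- sdm_config(gbm_nrounds = 300, rf_ntree = 200, ann_maxit = 150)
  for (tech in c("CTA", "ANN", "MDA", "GBM", "RF")) {
    m1 <- fit_sdm(tech, tab, cfg, seed = 11)
    m2 <- fit_sdm(tech, tab, cfg, seed = 11)
    p1 <- predict(m1, tab)
    expect_identical(p1, predict(m2, tab))
    expect_true(all(p1 >= 0 & p1 <= 1))
  }
  for (tech in c("RF", "GBM"))
    expect_gte(auc(predict(fit_sdm(tech, tab, cfg, seed = 1), tab),
                   tab$response), 0.99)
  expect_error(fit_sdm("GLM", tab), "arg")
  expect_error(fit_sdm("RF", make_table(data.frame(a = 1:5), rep(1, 5))),
               "degenerate")
})

test_that("a constant-only predictor yields chance-level suitability", {
  set.seed(77)
  tab <- make_table(data.frame(a = rep(2, 1000)), stats::rbinom(1000, 1, 0.5))
  for (tech in c("CTA", "ANN", "MDA", "GBM", "RF")) {
    p <- predict(fit_sdm(tech, tab, seed = 5), tab)
    expect_lt(abs(auc(p, tab$response) - 0.5), 0.1)
  }
})

test_that("split-sample evaluation: perfect model, null model, conventions", {
  tab <- separable_table(300, seed = 8)
  cfg <- sdm_config(rf_ntree = 200)
  ev <- evaluate_split("RF", tab, cfg, n_reps = 3, seed = 4)
  expect_equal(ev$auc_mean, 1)
  expect_equal(ev$auc_sd, 0)
  expect_false(is.null(ev$model$eval))

  # reproducible bit-exactly under the master seed
  ev2 <- evaluate_split("RF", tab, cfg, n_reps = 3, seed = 4)
  expect_identical(ev[c("auc_mean", "auc_sd", "tss_mean", "tss_sd")],
                   ev2[c("auc_mean", "auc_sd", "tss_mean", "tss_sd")])

  # labels independent of the predictors -> chance AUC
  set.seed(12)
  null_tab <- make_table(data.frame(a = stats::rnorm(500),
                                    b = stats::rnorm(500)),
                         stats::rbinom(500, 1, 0.5))
  evn <- evaluate_split("RF", null_tab, cfg, n_reps = 5, seed = 4)
  expect_lt(abs(evn$auc_mean - 0.5), 0.1)

  ev1 <- evaluate_split("CTA", tab, cfg, n_reps = 1, seed = 4)
  expect_equal(ev1$auc_sd, 0)
  expect_error(evaluate_split("RF", tab, calib_fraction = 1.2), "calib")
})

test_that("all five techniques recover a Gaussian niche signal
           (holdout AUC >= 0.8)", {
  set.seed(21)
  n <- 500
  x_pres <- stats::rnorm(n, 0, 1)       # presences around the niche optimum
  x_abs <- stats::runif(n, -8, 8)       # background spans the gradient
  tab <- make_table(
    data.frame(env = c(x_pres, x_abs),
               noise = stats::rnorm(2 * n)),
    rep(c(1L, 0L), each = n))
  cfg <- sdm_config(gbm_nrounds = 400, rf_ntree = 200, ann_maxit = 200)
  for (tech in c("CTA", "ANN", "MDA", "GBM", "RF")) {
    ev <- evaluate_split(tech, tab, cfg, n_reps = 2, seed = 9)
    expect_gte(ev$auc_mean, 0.8)
  }
})

test_that("permutation importance separates used from ignored predictors", {
  tab <- separable_table(500, seed = 33)
  cfg <- sdm_config(rf_ntree = 300)
  m <- fit_sdm("RF", tab, cfg, seed = 2)
  informative <- permutation_importance(m, tab, "a", seed = 6)
  expect_gt(informative$importance, 0.5)
  expect_lte(informative$importance, 1)

  # single-variable model: the ignored column cannot move predictions
  tab1 <- make_table(data.frame(a = tab$a, c = rep(1, nrow(tab))),
                     tab$response)
  m1 <- fit_sdm("RF", tab1, cfg, seed = 2)
  # permuting a constant column is the identity permutation
  expect_equal(permutation_importance(m1, tab1, "c", seed = 6)$importance, 0)
  expect_error(permutation_importance(m, tab, "zz"), "predictors")

  # constant predictions make the correlation degenerate -> importance 0
  const_m <- fit_sdm("RF", make_table(data.frame(a = rep(1, 50)),
                                      rep(c(0, 1), 25)), seed = 1)
  expect_equal(permutation_importance(const_m,
                                      make_table(data.frame(a = rep(1, 50)),
                                                 rep(c(0, 1), 25)),
                                      "a")$importance, 0)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  for (i in 1:5) {
    s <- stats::runif(80)
    l <- stats::rbinom(80, 1, 0.4)
    if (length(unique(l)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(s, l), ref)
  }
})
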
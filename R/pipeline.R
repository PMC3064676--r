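CLIMATE8 <- c("tm", "twm", "tcm", "tsd", "pm", "pwm", "pdm", "psd")

#' Default configuration for the two-stage modelling study
#'
#' Bundles every tunable of the synthetic world and of the modelling
#' pipeline. The world defaults describe a Mediterranean mountain
#' island of ~9000 land km2 with a 2700 m summit; two tree species
#' whose fundamental climatic niches extend from the coast to
#' mid-mountain but whose realized ranges were cleared below 1000 m
#' (95% of lowland cells removed), sparse relict coppices for the first
#' tree; and a bird requiring both suitable climate and host-tree
#' presence. Modelling defaults follow the standard protocol: 5 sets of
#' 5000 pseudo-absences, 70/30 split-sample evaluation repeated 5
#' times, all five techniques, consensus decay 1.6.
#'
#' @param ... named overrides (top-level keys only).
#' @return nested configuration list.
#' @export
study_config <- function(...) {
  cfg <- list(
    grid_size = c(128, 128),
    res = 1,                      # km per cell side
    relief = default_relief_params(),
    climate = default_climate_params(),
    pines = list(
      corsican_pine = list(
        niche = list(tm = list(opt = 11, sd = 5),
                     pm = list(opt = 1100, sd = 900)),
        truncation_elevation = 1000, clearing_fraction = 0.95,
        n_coppices = 20, n_presence = 300),
      maritime_pine = list(
        niche = list(tm = list(opt = 13, sd = 5),
                     pm = list(opt = 900, sd = 900)),
        truncation_elevation = 1000, clearing_fraction = 0.95,
        n_coppices = 0, n_presence = 200)
    ),
    bird = list(niche = list(tm = list(opt = 9, sd = 4)), n_presence = 150),
    scenarios = default_scenarios(),
    coarse_factor = 8,
    techniques = SDM_TECHNIQUES,
    n_pa = 5000, n_pa_sets = 5, n_reps = 5,
    decay = 1.6,
    occupancy_cutoff = 0.5,
    sdm = sdm_config()
  )
  # top-level keys are replaced wholesale (overriding `pines` means
  # supplying the full species list, not merging into the defaults)
  args <- list(...)
  for (nm in names(args)) cfg[[nm]] <- args[[nm]]
  cfg
}

#' Simulate a complete synthetic study world
#'
#' Generates the island landscape, the tree truths (with clearing and
#' coppices), the dependent bird truth, occurrence samples for every
#' species, and the coarse future-climate anomaly scenarios — the
#' synthetic stand-in for a full field + climate data set, with the
#' true fundamental and realized ranges known exactly.
#'
#' @param config see [study_config()].
#' @param seed master seed; all components derive child seeds from it.
#' @return object of class `study_world`.
#' @export
simulate_study_world <- function(config = study_config(), seed = 1) {
  landscape <- generate_island(config$grid_size, seed = seed,
                               relief_params = config$relief,
                               climate_params = config$climate,
                               res = config$res)
  pine_truths <- list()
  occ <- list()
  for (i in seq_along(config$pines)) {
    sp <- names(config$pines)[i]
    pc <- config$pines[[i]]
    tr <- define_virtual_species(
      landscape, pc$niche,
      truncation_elevation = pc$truncation_elevation,
      clearing_fraction = pc$clearing_fraction,
      n_coppices = pc$n_coppices,
      occupancy_cutoff = config$occupancy_cutoff,
      seed = child_seed(seed, 20 + i), species = sp)
    pine_truths[[sp]] <- tr
    occ[[sp]] <- sample_occurrences(tr, pc$n_presence,
                                    seed = child_seed(seed, 30 + i))
  }
  bird_truth <- generate_bird_truth(pine_truths, landscape,
                                    config$bird$niche,
                                    occupancy_cutoff = config$occupancy_cutoff,
                                    seed = child_seed(seed, 40),
                                    species = "bird")
  bird_occ <- sample_occurrences(bird_truth, config$bird$n_presence,
                                 seed = child_seed(seed, 41))
  structure(
    list(landscape = landscape, pine_truths = pine_truths,
         pine_occurrences = do.call(rbind, occ),
         bird_truth = bird_truth, bird_occurrences = bird_occ,
         scenarios = generate_scenarios(landscape, config$scenarios,
                                        coarse_factor = config$coarse_factor,
                                        seed = child_seed(seed, 50)),
         config = config, seed = seed),
    class = "study_world"
  )
}

#' @export
print.study_world <- function(x, ...) {
  cat("<study_world>\n")
  print(x$landscape)
  for (t in x$pine_truths) print(t)
  print(x$bird_truth)
  cat(sprintf("  scenarios: %s\n",
              paste(vapply(x$scenarios, `[[`, "", "id"), collapse = ", ")))
  invisible(x)
}

# maxTSS threshold resolved on the 100%-data consensus predictions:
# consensus suitability at the presence cells (label 1) and at every
# pseudo-absence cell of every run (label 0)
consensus_max_tss <- function(consensus_map, presences, pa_sets) {
  pres_s <- extract_at(consensus_map, presences$x, presences$y)
  pa <- do.call(rbind, pa_sets)
  abs_s <- extract_at(consensus_map, pa$x, pa$y)
  scores <- c(pres_s, abs_s)
  labels <- c(rep(1, length(pres_s)), rep(0, length(abs_s)))
  ok <- is.finite(scores)
  max_tss_threshold(scores[ok], labels[ok])
}

model_one_species <- function(species, presences, predictors_current,
                              predictors_future, mask, config, seed) {
  ens <- sdm_ensemble(predictors_current, presences, mask,
                      techniques = config$techniques,
                      n_pa = config$n_pa, n_pa_sets = config$n_pa_sets,
                      n_reps = config$n_reps, decay = config$decay,
                      config = config$sdm, seed = seed)
  current <- predict(ens, predictors_current)
  future_by_scenario <- lapply(predictors_future, function(p) predict(ens, p))
  list(ensemble = ens, current = current,
       future_by_scenario = future_by_scenario,
       future_mean = mean_across(future_by_scenario))
}

#' Stage one: ensemble models and threshold variants for the trees
#'
#' For each tree species: a rank-weighted ensemble on the ten
#' bioclimatic variables, consensus current and per-scenario future
#' suitability maps (future averaged over scenarios), and the three
#' binarization thresholds — maxTSS (resolved on the consensus
#' predictions at presence and pseudo-absence cells), LPT (lowest
#' consensus suitability at a presence), and LPT_coppice (lowest
#' consensus suitability at a relict coppice; skipped with a notice for
#' species without coppice records). Binary maps are produced for every
#' available threshold for the current, per-scenario future, and
#' scenario-mean future consensus maps.
#'
#' @param landscape the current `landscape`.
#' @param occurrences tree occurrence data.frame (`species`, `role`).
#' @param scenarios list of `scenario_anomaly` objects.
#' @param config see [study_config()].
#' @param seed master seed.
#' @return object of class `pine_stage`.
#' @export
run_pine_stage <- function(landscape, occurrences, scenarios,
                           config = study_config(), seed = 1) {
  bc_cur <- bioclim_stack(landscape)
  future_landscapes <- lapply(scenarios, downscale_anomaly,
                              baseline = landscape)
  bc_fut <- lapply(future_landscapes, bioclim_stack)
  mask <- landscape$elevation

  species <- unique(occurrences$species)
  out <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    sp_occ <- occurrences[occurrences$species == sp, , drop = FALSE]
    pres <- sp_occ[sp_occ$role == "presence", , drop = FALSE]
    mod <- model_one_species(sp, pres, bc_cur, bc_fut, mask, config,
                             seed = child_seed(seed, 60 + i))

    thresholds <- list(
      maxTSS = consensus_max_tss(mod$current, pres, mod$ensemble$pa_sets),
      LPT = lowest_presence_threshold(mod$current, sp_occ, "presence")
    )
    if (any(sp_occ$role == "coppice")) {
      thresholds$LPT_coppice <-
        lowest_presence_threshold(mod$current, sp_occ, "coppice")
    } else {
      message(sprintf("species '%s' has no coppice points; LPT_coppice skipped",
                      sp))
    }

    binaries <- lapply(thresholds, function(t) list(
      current = binarize(mod$current, t),
      future_mean = binarize(mod$future_mean, t),
      future_by_scenario = lapply(mod$future_by_scenario, binarize, t = t)
    ))

    out[[sp]] <- c(mod, list(thresholds = thresholds, binaries = binaries,
                             evaluation = summary(mod$ensemble)))
  }
  structure(list(species = out, bioclim_current = bc_cur,
                 bioclim_future = bc_fut, landscape = landscape,
                 scenarios = scenarios, config = config, seed = seed),
            class = "pine_stage")
}

#' @export
print.pine_stage <- function(x, ...) {
  cat("<pine_stage>\n")
  for (sp in names(x$species)) {
    s <- x$species[[sp]]
    cat(sprintf("  %s: thresholds %s\n", sp,
                paste(sprintf("%s=%.3f",
                              names(s$thresholds),
                              vapply(s$thresholds, `[[`, 0, "value")),
                      collapse = ", ")))
  }
  invisible(x)
}

# pine binary layer set for one threshold variant; species lacking the
# requested threshold fall back to their plain LPT (the coppice-based
# variant exists only for species with relict records)
pine_layers <- function(pine_stage, kind, slice, scenario = NULL) {
  lay <- list()
  for (sp in names(pine_stage$species)) {
    s <- pine_stage$species[[sp]]
    k <- if (kind %in% names(s$binaries)) kind else "LPT"
    b <- s$binaries[[k]]
    lay[[paste0("pine_", sp)]] <-
      if (slice == "current") b$current
      else if (is.null(scenario)) b$future_mean
      else b$future_by_scenario[[scenario]]
  }
  lay
}

#' Stage two: bird model fit on observed habitat, projected under the
#' three tree-threshold variants
#'
#' The bird ensemble is fit on the eight basic climate variables plus
#' one binary layer per tree species binarized at the maxTSS threshold
#' (the variant closest to the observed tree distribution). It is then
#' projected — for the current climate and for each future scenario
#' (averaged afterwards) — substituting the tree layers binarized under
#' each variant in turn: maxTSS, LPT, LPT_coppice. The bird's own
#' thresholds are resolved on the variant's current consensus map: the
#' LPT at the bird presences for every variant, plus the maxTSS for the
#' conventional all-TSS analysis. Range metrics are computed for the
#' four variant columns (bird maxTSS x tree maxTSS; bird LPT x tree
#' maxTSS / LPT / LPT_coppice).
#'
#' @param landscape the current `landscape`.
#' @param bird_occurrences bird occurrence data.frame.
#' @param pine_stage result of [run_pine_stage()].
#' @param config,seed as in [run_pine_stage()].
#' @return object of class `bird_stage` with `maps` (per variant:
#'   current, future), `thresholds`, `metrics` (per Table-style variant
#'   column) and the fitted `ensemble`.
#' @export
run_bird_stage <- function(landscape, bird_occurrences, pine_stage,
                           config = study_config(), seed = 1) {
  bc8_cur <- pine_stage$bioclim_current[CLIMATE8]
  bc8_fut <- lapply(pine_stage$bioclim_future, `[`, CLIMATE8)
  mask <- landscape$elevation
  pres <- bird_occurrences[bird_occurrences$role == "presence", , drop = FALSE]

  fit_predictors <- c(bc8_cur, pine_layers(pine_stage, "maxTSS", "current"))
  ens <- sdm_ensemble(fit_predictors, pres, mask,
                      techniques = config$techniques,
                      n_pa = config$n_pa, n_pa_sets = config$n_pa_sets,
                      n_reps = config$n_reps, decay = config$decay,
                      config = config$sdm, seed = child_seed(seed, 70))

  variants <- c("maxTSS", "LPT", "LPT_coppice")
  maps <- list()
  for (v in variants) {
    cur <- predict(ens, c(bc8_cur, pine_layers(pine_stage, v, "current")))
    fut_sc <- lapply(names(pine_stage$scenarios), function(sc)
      predict(ens, c(bc8_fut[[sc]], pine_layers(pine_stage, v, "future", sc))))
    maps[[v]] <- list(current = cur, future = mean_across(fut_sc),
                      future_by_scenario = fut_sc)
  }

  thresholds <- list(
    maxTSS = consensus_max_tss(maps$maxTSS$current, pres, ens$pa_sets)
  )
  for (v in variants) {
    thresholds[[paste0("LPT_", v)]] <-
      lowest_presence_threshold(maps[[v]]$current, bird_occurrences,
                                "presence")
  }

  pixel_area <- landscape$pixel_area_km2
  metrics <- list(
    TSS_TSS = range_metrics(maps$maxTSS$current, maps$maxTSS$future,
                            thresholds$maxTSS, pres, pixel_area),
    LPT_TSS = range_metrics(maps$maxTSS$current, maps$maxTSS$future,
                            thresholds$LPT_maxTSS, pres, pixel_area),
    LPT_LPT = range_metrics(maps$LPT$current, maps$LPT$future,
                            thresholds$LPT_LPT, pres, pixel_area),
    LPT_LPTcoppice = range_metrics(maps$LPT_coppice$current,
                                   maps$LPT_coppice$future,
                                   thresholds$LPT_LPT_coppice, pres,
                                   pixel_area)
  )

  structure(list(ensemble = ens, maps = maps, thresholds = thresholds,
                 metrics = metrics, evaluation = summary(ens),
                 config = config, seed = seed),
            class = "bird_stage")
}

#' @export
print.bird_stage <- function(x, ...) {
  cat("<bird_stage>\n")
  print(build_report(x$metrics))
  invisible(x)
}

#' Range and suitability metrics for a current/future map pair
#'
#' The range is the set of cells with suitability at or above the
#' threshold; its area is the cell count times the pixel area, its
#' mean suitability is averaged over those cells (NA for an empty
#' range). Presence-point retention is the fraction of presence points
#' whose future-map suitability is at or above the threshold, and the
#' presence-point mean suitabilities are computed on the raw
#' (unfiltered) maps.
#'
#' @param current,future aligned suitability `raster_grid`s.
#' @param threshold a `threshold_spec` (or number); the same cutoff is
#'   applied to both time slices.
#' @param presences presence occurrence data.frame.
#' @param pixel_area km2 per cell.
#' @return object of class `range_metrics` (a named list of the seven
#'   summary values).
#' @export
range_metrics <- function(current, future, threshold, presences,
                          pixel_area = 1) {
  rg_check_aligned(list(current, future))
  v <- if (inherits(threshold, "threshold_spec")) threshold$value
       else threshold
  cur_in <- is.finite(current$values) & current$values >= v
  fut_in <- is.finite(future$values) & future$values >= v
  pres <- presences[presences$role == "presence", , drop = FALSE]
  cur_at <- extract_at(current, pres$x, pres$y)
  fut_at <- extract_at(future, pres$x, pres$y)
  ok <- is.finite(cur_at) & is.finite(fut_at)
  structure(list(
    current_range_km2 = sum(cur_in) * pixel_area,
    future_range_km2 = sum(fut_in) * pixel_area,
    current_mean_suitability = if (any(cur_in))
      mean(current$values[cur_in]) else NA_real_,
    future_mean_suitability = if (any(fut_in))
      mean(future$values[fut_in]) else NA_real_,
    prop_presences_in_future = mean(fut_at[ok] >= v),
    mean_current_suit_at_presences = mean(cur_at[ok]),
    mean_future_suit_at_presences = mean(fut_at[ok]),
    threshold = v
  ), class = "range_metrics")
}

#' @export
print.range_metrics <- function(x, ...) {
  cat(sprintf(
    "<range_metrics> range %.0f -> %.0f km2 (%+d%%), mean suit %.2f -> %.2f, presences retained %.2f\n",
    x$current_range_km2, x$future_range_km2,
    if (x$current_range_km2 > 0)
      percent_change(x$current_range_km2, x$future_range_km2) else NA,
    x$current_mean_suitability, x$future_mean_suitability,
    x$prop_presences_in_future))
  invisible(x)
}

#' Signed percent change between a current and a future value
#'
#' `(future - current) / current * 100`, rounded to the nearest integer
#' (the reporting convention for range and suitability changes).
#'
#' @param current_value baseline value, must be > 0.
#' @param future_value projected value.
#' @return integer-rounded signed percent.
#' @export
percent_change <- function(current_value, future_value) {
  if (any(current_value <= 0)) stop("current_value must be > 0")
  round((future_value - current_value) / current_value * 100)
}

#' Summary table of range metrics across threshold variants
#'
#' One column per (bird threshold, tree threshold) variant and one row
#' per metric: current/future range, current/future mean suitability,
#' proportion of presence points in the future range, and mean
#' current/future suitability at the presence points.
#'
#' @param metrics named list of `range_metrics` (missing variants are
#'   omitted with a warning).
#' @param file optional path to also write the table as CSV.
#' @return data.frame (rows = metrics, columns = variants).
#' @export
build_report <- function(metrics, file = NULL) {
  rows <- c(current_range_km2 = "Current range (km2)",
            future_range_km2 = "Future range (km2)",
            current_mean_suitability = "Current mean suitability",
            future_mean_suitability = "Future mean suitability",
            prop_presences_in_future = "Proportion of presence points included in the future distribution",
            mean_current_suit_at_presences = "Mean current suitability of presence points",
            mean_future_suit_at_presences = "Mean future suitability of the presence points")
  keep <- !vapply(metrics, is.null, TRUE)
  if (any(!keep))
    warning("variants omitted from the report: ",
            paste(names(metrics)[!keep], collapse = ", "))
  metrics <- metrics[keep]
  tab <- vapply(metrics, function(m) unlist(m[names(rows)]),
                numeric(length(rows)))
  tab <- as.data.frame(tab)
  rownames(tab) <- unname(rows)
  if (!is.null(file)) {
    utils::write.csv(cbind(metric = rownames(tab), tab), file,
                     row.names = FALSE)
  }
  tab
}

#' Run the full two-stage study on a synthetic world
#'
#' Simulates the world, derives climate, runs the tree stage and the
#' bird stage, and assembles the variant report. Fully deterministic
#' under the master seed.
#'
#' @param config see [study_config()].
#' @param seed master seed.
#' @return object of class `niche_study` with `world`, `pine_stage`,
#'   `bird_stage`, `report`.
#' @export
run_study <- function(config = study_config(), seed = 1) {
  world <- simulate_study_world(config, seed)
  pine_stage <- run_pine_stage(world$landscape, world$pine_occurrences,
                               world$scenarios, config,
                               seed = child_seed(seed, 2))
  bird_stage <- run_bird_stage(world$landscape, world$bird_occurrences,
                               pine_stage, config,
                               seed = child_seed(seed, 3))
  structure(list(world = world, pine_stage = pine_stage,
                 bird_stage = bird_stage,
                 report = build_report(bird_stage$metrics),
                 config = config, seed = seed),
            class = "niche_study")
}

#' @export
print.niche_study <- function(x, ...) {
  cat("<niche_study>\n\nRange metrics by threshold variant (columns:",
      "bird threshold x tree threshold):\n")
  print(round(x$report, 3))
  invisible(x)
}

#' @export
summary.niche_study <- function(object, ...) {
  cat("Tree-stage evaluation (mean over runs and splits):\n")
  for (sp in names(object$pine_stage$species))
    cat(sprintf("  %s: AUC %.3f, TSS %.3f\n", sp,
                max(object$pine_stage$species[[sp]]$evaluation$auc),
                max(object$pine_stage$species[[sp]]$evaluation$tss)))
  cat("Bird-stage evaluation:\n")
  cat(sprintf("  best technique AUC %.3f\n",
              max(object$bird_stage$evaluation$auc)))
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
plot.niche_study <- function(x, variant = "LPT_coppice", ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  m <- x$bird_stage$maps[[variant]]
  plot(m$current, main = paste("bird current,", variant))
  plot(m$future, main = paste("bird future,", variant))
  invisible(x)
}

#' Fundamental-niche recovery diagnostics for a tree species
#'
#' Quantifies the study's central contrast on a synthetic world where
#' the truth is known: per threshold variant, the recall of the true
#' fundamental range by the binary map (fraction of fundamental cells
#' recovered) and the TSS of the binary map against the true realized
#' range. The coppice-informed LPT is expected to recover the
#' fundamental range better, while the maxTSS binary matches the
#' realized range better.
#'
#' @param pine_stage a `pine_stage`.
#' @param truth the species' `virtual_species_truth`.
#' @param species species name within the stage.
#' @return data.frame with columns `kind`, `fundamental_recall`,
#'   `tss_vs_realized`.
#' @export
recovery_summary <- function(pine_stage, truth, species) {
  s <- pine_stage$species[[species]]
  if (is.null(s)) stop("unknown species in pine stage")
  land <- is.finite(truth$fundamental_range$values)
  fund <- truth$fundamental_range$values[land] == 1
  real <- truth$realized_range$values[land] == 1
  out <- lapply(names(s$binaries), function(k) {
    b <- s$binaries[[k]]$current$values[land] == 1
    data.frame(
      kind = k,
      fundamental_recall = sum(b & fund) / sum(fund),
      tss_vs_realized = mean(b[real]) + mean(!b[!real]) - 1
    )
  })
  do.call(rbind, out)
}
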
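#' Rank-based geometric decay weights for model consensus
#'
#' The model ranked `r` (1 = best) receives weight proportional to
#' `decay^(n_models - r)`, normalized to sum to one. With five models
#' and the canonical decay of 1.6 this yields weights 0.41, 0.26,
#' 0.16, 0.10, 0.06 (2-decimal rounding); decay 1 gives uniform
#' weights.
#'
#' @param n_models number of ranked models (>= 1).
#' @param decay geometric decay, >= 1.
#' @return data.frame with columns `rank`, `weight` (class
#'   `weight_vector`); weights sum to 1 and strictly decrease with rank
#'   when `decay > 1`.
#' @export
decay_weights <- function(n_models, decay = 1.6) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (decay < 1) stop("decay must be >= 1")
  r <- seq_len(n_models)
  w <- decay^(n_models - r)
  w <- w / sum(w)
  structure(data.frame(rank = r, weight = w),
            class = c("weight_vector", "data.frame"), decay = decay)
}

#' Order fitted models by predictive performance
#'
#' Descending by the mean of the chosen criterion; ties broken by the
#' other criterion, then by the fixed technique order CTA, ANN, MDA,
#' GBM, RF.
#'
#' @param models list of evaluated `sdm_model`s (each with `$eval`).
#' @param criterion `"AUC"` (default, used for model selection) or
#'   `"TSS"`.
#' @return the models reordered best-first, with a `ranking` attribute
#'   (data.frame of technique, criterion means, rank).
#' @export
rank_models <- function(models, criterion = c("AUC", "TSS")) {
  criterion <- match.arg(criterion)
  if (any(vapply(models, function(m) is.null(m$eval), TRUE)))
    stop("all models must be evaluated before ranking")
  aucs <- vapply(models, function(m) m$eval$auc_mean, 0)
  tsss <- vapply(models, function(m) m$eval$tss_mean, 0)
  tech <- vapply(models, function(m) m$technique, "")
  tech_order <- match(tech, SDM_TECHNIQUES)
  ord <- if (criterion == "AUC") order(-aucs, -tsss, tech_order)
         else order(-tsss, -aucs, tech_order)
  out <- models[ord]
  attr(out, "ranking") <- data.frame(
    technique = tech[ord], auc = aucs[ord], tss = tsss[ord],
    rank = seq_along(ord))
  out
}

#' Weighted cellwise mean of suitability maps
#'
#' Computes the consensus map `sum_i w_i * map_i`. A cell is nodata in
#' the output if it is nodata in any member.
#'
#' @param maps list of aligned `raster_grid`s.
#' @param weights a `weight_vector` (or numeric vector) matching
#'   `maps` in length; `maps[[i]]` is paired with the i-th weight.
#' @return a `raster_grid`.
#' @export
weighted_consensus <- function(maps, weights) {
  w <- if (is.data.frame(weights)) weights$weight else as.numeric(weights)
  if (length(maps) != length(w)) stop("|maps| must equal |weights|")
  rg_check_aligned(maps)
  acc <- maps[[1]]$values * w[1]
  for (i in seq_along(maps)[-1]) acc <- acc + maps[[i]]$values * w[i]
  rg_like(maps[[1]], acc)
}

#' Unweighted cellwise mean of suitability maps
#'
#' Equivalent to [weighted_consensus()] with uniform weights; used to
#' average consensus maps across pseudo-absence runs and across climate
#' scenarios.
#'
#' @param maps list of aligned `raster_grid`s.
#' @return a `raster_grid`.
#' @export
mean_across <- function(maps) {
  weighted_consensus(maps, rep(1 / length(maps), length(maps)))
}

#' Fit a rank-weighted ensemble of suitability learners
#'
#' The modelling core of the pipeline: for each of `n_pa_sets`
#' pseudo-absence sets, every technique is evaluated by repeated
#' stratified split-sampling ([evaluate_split()]), refit on all rows,
#' ranked by mean AUC within the run, and assigned geometric decay
#' weights. `predict()` on the ensemble computes, per run, the weighted
#' consensus of the member predictions, then the unweighted mean across
#' runs.
#'
#' @param predictors named list of aligned `raster_grid`s used to fit.
#' @param presences presence occurrence data.frame.
#' @param mask `raster_grid` of eligible cells for pseudo-absences.
#' @param techniques subset of `c("CTA","ANN","MDA","GBM","RF")`.
#' @param n_pa pseudo-absences per set (default 5000).
#' @param n_pa_sets number of pseudo-absence sets (default 5).
#' @param n_reps evaluation split repetitions (default 5).
#' @param decay consensus decay (default 1.6).
#' @param config learner configuration, see [sdm_config()].
#' @param seed master seed.
#' @return object of class `sdm_ensemble`.
#' @export
sdm_ensemble <- function(predictors, presences, mask,
                         techniques = SDM_TECHNIQUES,
                         n_pa = 5000, n_pa_sets = 5, n_reps = 5,
                         decay = 1.6, config = sdm_config(), seed = 1) {
  techniques <- match.arg(techniques, SDM_TECHNIQUES, several.ok = TRUE)
  pa_sets <- sample_pseudo_absences(mask, presences, n = n_pa,
                                    n_sets = n_pa_sets, seed = seed)
  runs <- vector("list", n_pa_sets)
  tables <- vector("list", n_pa_sets)
  for (s in seq_len(n_pa_sets)) {
    tab <- extract_training_table(predictors, presences, pa_sets[[s]])
    tables[[s]] <- tab
    models <- vector("list", length(techniques))
    for (j in seq_along(techniques)) {
      ev <- evaluate_split(techniques[j], tab, config = config,
                           n_reps = n_reps,
                           seed = child_seed(seed, 3000 + 100 * s + j))
      models[[j]] <- ev$model
    }
    ranked <- rank_models(models, "AUC")
    runs[[s]] <- list(models = ranked,
                      ranking = attr(ranked, "ranking"),
                      weights = decay_weights(length(ranked), decay))
  }
  structure(
    list(runs = runs, pa_sets = pa_sets, tables = tables,
         techniques = techniques, predictors = names(predictors),
         decay = decay, seed = seed),
    class = "sdm_ensemble"
  )
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %d techniques x %d pseudo-absence runs, decay %.2f\n",
              length(x$techniques), length(x$runs), x$decay))
  print(summary(x))
  invisible(x)
}

#' Per-technique evaluation summary of an ensemble
#'
#' @param object an `sdm_ensemble`.
#' @param ... unused.
#' @return data.frame of mean AUC/TSS per technique, aggregated over
#'   pseudo-absence runs (each run's value is itself a mean over split
#'   repetitions).
#' @export
summary.sdm_ensemble <- function(object, ...) {
  per_run <- do.call(rbind, lapply(object$runs, `[[`, "ranking"))
  agg <- stats::aggregate(cbind(auc, tss) ~ technique, per_run, mean)
  agg$auc_sd_runs <- stats::aggregate(auc ~ technique, per_run, stats::sd)$auc
  agg$tss_sd_runs <- stats::aggregate(tss ~ technique, per_run, stats::sd)$tss
  agg[order(-agg$auc), ]
}

#' Consensus suitability prediction from an ensemble
#'
#' @param object an `sdm_ensemble`.
#' @param newdata named list of aligned predictor `raster_grid`s (a
#'   consensus `raster_grid` is returned) or a data.frame (a numeric
#'   vector is returned).
#' @param ... unused.
#' @return consensus suitability, in \[0,1\] wherever defined.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  run_maps <- lapply(object$runs, function(run) {
    member <- lapply(run$models, predict, newdata = newdata)
    if (is.data.frame(newdata)) {
      as.numeric(crossprod(do.call(rbind, member), run$weights$weight))
    } else {
      weighted_consensus(member, run$weights)
    }
  })
  if (is.data.frame(newdata)) {
    rowMeans(do.call(cbind, run_maps))
  } else {
    mean_across(run_maps)
  }
}
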
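SDM_TECHNIQUES <- c("CTA", "ANN", "MDA", "GBM", "RF")

#' Default learner configuration
#'
#' Hyperparameters of the five suitability learners. The defaults are:
#' CTA — cost-complexity pruning by internal cross-validation (50 folds,
#' capped at n-1); ANN — single hidden layer of 8 units, weight decay
#' 0.01, mean of 3 independently initialized fits; MDA — per-class
#' Gaussian mixtures with 3 components per class; GBM — 2000 boosted
#' depth-3 trees with shrinkage 0.01; RF — 500 trees.
#'
#' @param ... named overrides.
#' @return named list of hyperparameters.
#' @export
sdm_config <- function(...) {
  cfg <- list(
    cta_xval = 50,
    ann_size = 8, ann_decay = 0.01, ann_maxit = 300, ann_runs = 3,
    mda_components = 3,
    gbm_nrounds = 2000, gbm_eta = 0.01, gbm_depth = 3,
    rf_ntree = 500
  )
  utils::modifyList(cfg, list(...))
}

#' Sample pseudo-absence point sets from a landscape
#'
#' Draws `n_sets` independent uniform samples of `n` cells, without
#' replacement within a set, from the valid (non-nodata) cells that do
#' not host a presence point. Deterministic per seed.
#'
#' @param mask a `raster_grid`; cells with finite values are eligible.
#' @param presences occurrence data.frame (only `role == "presence"`
#'   rows are used to exclude cells).
#' @param n points per set (default 5000).
#' @param n_sets number of sets (default 5).
#' @param seed integer seed.
#' @return list of `n_sets` data.frames with `x`, `y`, `species`, `role
#'   = "pseudo_absence"`.
#' @export
sample_pseudo_absences <- function(mask, presences, n = 5000, n_sets = 5,
                                   seed = 1) {
  pres <- presences[presences$role == "presence", , drop = FALSE]
  idx <- cells_for_points(mask, pres$x, pres$y)
  pres_cells <- (idx$col - 1L) * nrow(mask$values) + idx$row
  eligible <- setdiff(which(is.finite(mask$values)), pres_cells)
  if (n > length(eligible))
    stop(sprintf("need %d pseudo-absence cells but only %d are eligible (short by %d)",
                 n, length(eligible), n - length(eligible)))
  nr <- nrow(mask$values)
  out <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(child_seed(seed, 40 + s))
    picked <- eligible[sample.int(length(eligible), n)]
    rows <- ((picked - 1L) %% nr) + 1L
    cols <- ((picked - 1L) %/% nr) + 1L
    ctr <- cell_centers(mask, rows, cols)
    out[[s]] <- data.frame(x = ctr$x, y = ctr$y,
                           species = rep("background", n),
                           role = rep("pseudo_absence", n),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Build a model training table from predictor grids and points
#'
#' One row per point, with the predictor values at the point's cell and
#' a binary response (1 = presence, 0 = absence). Points falling on
#' nodata cells are dropped; the dropped count is attached as attribute
#' `n_dropped`. Presences and absences sharing a cell are both kept.
#'
#' @param predictors named list of aligned `raster_grid`s.
#' @param presences,absences occurrence data.frames.
#' @return data.frame with the predictor columns, `response`, `weight`,
#'   `point_id`; class `training_table`.
#' @export
extract_training_table <- function(predictors, presences, absences) {
  rg_check_aligned(predictors)
  pts <- rbind(
    data.frame(x = presences$x, y = presences$y, response = 1),
    data.frame(x = absences$x, y = absences$y, response = 0)
  )
  X <- vapply(predictors, function(g) extract_at(g, pts$x, pts$y),
              numeric(nrow(pts)))
  X <- as.data.frame(X)
  names(X) <- names(predictors)
  keep <- stats::complete.cases(X)
  if (!any(keep)) stop("all points fall on nodata cells")
  tab <- cbind(X[keep, , drop = FALSE],
               response = pts$response[keep],
               weight = 1,
               point_id = seq_len(nrow(pts))[keep])
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- sum(!keep)
  attr(tab, "predictors") <- names(predictors)
  class(tab) <- c("training_table", "data.frame")
  tab
}

table_predictors <- function(table) {
  p <- attr(table, "predictors")
  if (is.null(p)) setdiff(names(table), c("response", "weight", "point_id"))
  else p
}

check_table <- function(table) {
  preds <- table_predictors(table)
  if (!all(table$response %in% c(0, 1))) stop("response must be 0/1")
  if (length(unique(table$response)) < 2)
    stop("training table is degenerate: single response class")
  if (any(!stats::complete.cases(table[preds])))
    stop("training table contains missing predictor values")
  preds
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Fit one suitability learner
#'
#' Fits one of the five niche-modelling techniques to a presence /
#' (pseudo-)absence training table and returns a continuous suitability
#' model: `CTA` classification tree (rpart) pruned by internal
#' cross-validated cost-complexity; `ANN` feed-forward neural network
#' (nnet), predictions averaged over 3 independently initialized fits;
#' `MDA` mixture discriminant analysis (per-class Gaussian mixtures,
#' mclust); `GBM` gradient-boosted regression trees (xgboost); `RF`
#' random forest (randomForest). All techniques emit class-probability
#' style suitabilities clamped to \[0,1\]. Deterministic per seed.
#'
#' @param technique one of `"CTA"`, `"ANN"`, `"MDA"`, `"GBM"`, `"RF"`.
#' @param table a `training_table` with both classes present.
#' @param config see [sdm_config()].
#' @param seed integer seed.
#' @return object of class `sdm_model` with elements `technique`,
#'   `fit`, `predictors`, `seed`, and (after evaluation) `eval`.
#' @export
fit_sdm <- function(technique, table, config = sdm_config(), seed = 1) {
  technique <- match.arg(technique, SDM_TECHNIQUES)
  preds <- check_table(table)
  X <- as.data.frame(table[preds])
  y <- table$response
  # no predictor varies: nothing to learn, predict the prevalence
  if (all(vapply(X, function(col) stats::sd(col) == 0, TRUE))) {
    return(structure(list(technique = technique,
                          fit = list(constant = mean(y)),
                          predictors = preds, seed = seed, config = config,
                          eval = NULL),
                     class = c("sdm_constant", "sdm_model")))
  }
  set.seed(child_seed(seed, 7))

  fit <- switch(
    technique,
    CTA = {
      dat <- cbind(X, .resp = factor(y, levels = c(0, 1)))
      xval <- max(2L, min(config$cta_xval, nrow(dat) - 1L))
      tr <- rpart::rpart(.resp ~ ., data = dat, method = "class",
                         control = rpart::rpart.control(xval = xval,
                                                        cp = 1e-4))
      cpt <- tr$cptable
      best <- cpt[which.min(cpt[, "xerror"]), "CP"]
      rpart::prune(tr, cp = best)
    },
    ANN = {
      ctr <- vapply(X, mean, 0); scl <- vapply(X, stats::sd, 0)
      scl[scl == 0] <- 1
      Xs <- scale(as.matrix(X), center = ctr, scale = scl)
      nets <- lapply(seq_len(config$ann_runs), function(i) {
        nnet::nnet(Xs, y, size = config$ann_size, decay = config$ann_decay,
                   maxit = config$ann_maxit, entropy = TRUE, trace = FALSE)
      })
      list(nets = nets, center = ctr, scale = scl)
    },
    MDA = {
      G <- config$mda_components
      # fall back to fewer components if a class is too small for G
      Gs <- max(1L, min(G, floor(min(table(y)) / 4)))
      mclust::MclustDA(as.matrix(X), class = factor(y, levels = c(0, 1)),
                       G = seq_len(Gs), modelType = "MclustDA",
                       verbose = FALSE)
    },
    GBM = {
      xgboost::xgboost(as.matrix(X), factor(y, levels = c(0, 1)),
                       nrounds = config$gbm_nrounds,
                       learning_rate = config$gbm_eta,
                       max_depth = config$gbm_depth,
                       nthreads = 1, verbosity = 0,
                       seed = child_seed(seed, 8))
    },
    RF = randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = config$rf_ntree)
  )

  structure(list(technique = technique, fit = fit, predictors = preds,
                 seed = seed, config = config, eval = NULL),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s on %d predictors", x$technique,
              length(x$predictors)))
  if (!is.null(x$eval))
    cat(sprintf(" | AUC %.3f+-%.3f TSS %.3f+-%.3f",
                x$eval$auc_mean, x$eval$auc_sd,
                x$eval$tss_mean, x$eval$tss_sd))
  cat("\n")
  invisible(x)
}

#' Predict suitability from a fitted learner
#'
#' @param object an `sdm_model`.
#' @param newdata a data.frame with the training predictors, or a named
#'   list of aligned `raster_grid`s (then a suitability `raster_grid`
#'   is returned, nodata preserved).
#' @param ... unused.
#' @return numeric vector in \[0,1\], or a `raster_grid`.
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.data.frame(newdata) &&
      inherits(newdata[[1]], "raster_grid")) {
    grids <- newdata[object$predictors]
    if (any(vapply(grids, is.null, TRUE)))
      stop("prediction grids missing some training predictors")
    rg_check_aligned(grids)
    df <- as.data.frame(lapply(grids, function(g) as.vector(g$values)))
    ok <- stats::complete.cases(df)
    out <- rep(NA_real_, nrow(df))
    if (any(ok)) out[ok] <- predict_rows(object, df[ok, , drop = FALSE])
    return(rg_like(grids[[1]], out))
  }
  predict_rows(object, as.data.frame(newdata)[object$predictors])
}

predict_rows <- function(object, X) {
  if (!is.null(object$fit$constant))
    return(rep(clamp01(object$fit$constant), nrow(X)))
  p <- switch(
    object$technique,
    CTA = stats::predict(object$fit, newdata = X, type = "prob")[, "1"],
    ANN = {
      Xs <- scale(as.matrix(X), center = object$fit$center,
                  scale = object$fit$scale)
      rowMeans(vapply(object$fit$nets,
                      function(nn) as.vector(stats::predict(nn, Xs)),
                      numeric(nrow(X))))
    },
    MDA = {
      z <- stats::predict(object$fit, newdata = as.matrix(X))$z
      z[, "1"]
    },
    GBM = stats::predict(object$fit, as.matrix(X), type = "response"),
    RF = stats::predict(object$fit, newdata = X, type = "prob")[, "1"]
  )
  clamp01(as.numeric(p))
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Probability that a randomly chosen presence scores above a randomly
#' chosen absence, counting ties as one half.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 vector (both classes required).
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic at a threshold
#'
#' Sensitivity + specificity - 1, predicting presence where
#' `score >= threshold`.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 vector (both classes required).
#' @param threshold decision threshold.
#' @return TSS in \[-1,1\].
#' @export
tss <- function(scores, labels, threshold) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("TSS needs both classes")
  pred <- scores >= threshold
  sens <- mean(pred[labels == 1])
  spec <- mean(!pred[labels == 0])
  sens + spec - 1
}

#' Split-sample evaluation of a learner (AUC and TSS)
#'
#' Per repetition: a class-stratified random split reserves
#' `1 - calib_fraction` of the rows for evaluation, the learner is fit
#' on the calibration part, and the holdout is scored with AUC and with
#' TSS at the holdout's own TSS-maximizing threshold. Means and
#' standard deviations are reported across repetitions (sd 0 for a
#' single repetition), and the final model is refit on 100% of the rows
#' with the evaluation summary attached.
#'
#' @param technique,table,config,seed as in [fit_sdm()].
#' @param calib_fraction calibration fraction in (0,1), default 0.7.
#' @param n_reps number of split repetitions, default 5.
#' @return list with `model` (the 100%-data refit, with `$eval`),
#'   `auc_mean`, `auc_sd`, `tss_mean`, `tss_sd`, and `reps` (per-rep
#'   data.frame).
#' @export
evaluate_split <- function(technique, table, config = sdm_config(),
                           calib_fraction = 0.7, n_reps = 5, seed = 1) {
  if (calib_fraction <= 0 || calib_fraction >= 1)
    stop("calib_fraction must be in (0,1)")
  check_table(table)
  i1 <- which(table$response == 1)
  i0 <- which(table$response == 0)

  rep_stats <- data.frame(rep = seq_len(n_reps), auc = NA_real_,
                          tss = NA_real_, threshold = NA_real_)
  for (r in seq_len(n_reps)) {
    split_seed <- child_seed(seed, 500 + r)
    holdout_ok <- FALSE
    for (try in 1:5) {
      set.seed(child_seed(split_seed, try))
      c1 <- i1[sample.int(length(i1), max(1, round(calib_fraction * length(i1))))]
      c0 <- i0[sample.int(length(i0), max(1, round(calib_fraction * length(i0))))]
      hold <- setdiff(seq_len(nrow(table)), c(c1, c0))
      if (sum(table$response[hold] == 1) > 0 &&
          sum(table$response[hold] == 0) > 0) { holdout_ok <- TRUE; break }
    }
    if (!holdout_ok) stop("could not produce a holdout containing both classes")
    calib <- table[c(c1, c0), , drop = FALSE]
    attr(calib, "predictors") <- table_predictors(table)
    class(calib) <- class(table)
    m <- fit_sdm(technique, calib, config, seed = child_seed(seed, 600 + r))
    sc <- predict(m, table[hold, , drop = FALSE])
    lb <- table$response[hold]
    th <- max_tss_threshold(sc, lb)
    rep_stats$auc[r] <- auc(sc, lb)
    rep_stats$tss[r] <- tss(sc, lb, th$value)
    rep_stats$threshold[r] <- th$value
  }

  final <- fit_sdm(technique, table, config, seed = child_seed(seed, 700))
  final$eval <- list(
    auc_mean = mean(rep_stats$auc),
    auc_sd = if (n_reps > 1) stats::sd(rep_stats$auc) else 0,
    tss_mean = mean(rep_stats$tss),
    tss_sd = if (n_reps > 1) stats::sd(rep_stats$tss) else 0,
    n_reps = n_reps
  )
  c(final$eval[c("auc_mean", "auc_sd", "tss_mean", "tss_sd")],
    list(model = final, reps = rep_stats))
}

#' Permutation importance of one predictor
#'
#' One minus the Pearson correlation between the model's standard
#' predictions on the table and its predictions after permuting the
#' given predictor column, averaged over `n_permutations` random
#' permutations and clamped to \[0,1\]. If either prediction vector is
#' constant the correlation is degenerate and the importance is 0.
#'
#' @param model a fitted `sdm_model`.
#' @param table the training table.
#' @param variable predictor name.
#' @param n_permutations default 3.
#' @param seed integer seed.
#' @return list with `variable` and `importance`.
#' @export
permutation_importance <- function(model, table, variable,
                                   n_permutations = 3, seed = 1) {
  if (!variable %in% model$predictors)
    stop("variable not among the training predictors")
  X <- as.data.frame(table[model$predictors])
  base <- predict(model, X)
  vals <- numeric(n_permutations)
  for (k in seq_len(n_permutations)) {
    set.seed(child_seed(seed, 800 + k))
    Xp <- X
    Xp[[variable]] <- Xp[[variable]][sample.int(nrow(Xp))]
    perm <- predict(model, Xp)
    if (stats::sd(base) == 0 || stats::sd(perm) == 0) {
      vals[k] <- 0
    } else {
      vals[k] <- 1 - stats::cor(base, perm)
    }
  }
  list(variable = variable, importance = clamp01(mean(vals)))
}
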
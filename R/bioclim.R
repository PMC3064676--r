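# stack 12 monthly grids into an (ncell x 12) matrix, after checking
# alignment; NA (nodata) propagates through every derived variable
month_matrix <- function(monthly) {
  if (length(monthly) != 12) stop("need exactly 12 monthly grids")
  rg_check_aligned(monthly)
  vapply(monthly, function(g) as.vector(g$values), numeric(length(monthly[[1]]$values)))
}

#' Derive the eight basic bioclimatic variables from monthly climate
#'
#' From 12 monthly mean temperature grids (degC) and 12 monthly
#' precipitation grids (mm) computes: `tm` annual mean temperature,
#' `twm`/`tcm` mean temperature of the warmest/coldest month, `tsd`
#' temperature seasonality (plain standard deviation of the 12 monthly
#' means, degC — not the x100 convention of some bioclim datasets),
#' `pm` annual precipitation, `pwm`/`pdm` wettest/driest month
#' precipitation, `psd` precipitation seasonality (coefficient of
#' variation sd/mean; 0 where the annual mean is 0). A nodata cell in
#' any month is nodata in every output.
#'
#' @param monthly_t,monthly_p lists of 12 aligned `raster_grid`s.
#' @return named list of eight `raster_grid`s.
#' @export
derive_bioclim <- function(monthly_t, monthly_p) {
  Tm <- month_matrix(monthly_t)
  Pm <- month_matrix(monthly_p)
  rg_check_aligned(c(monthly_t[1], monthly_p[1]))
  tmpl <- monthly_t[[1]]

  t_mean <- rowMeans(Tm)
  t_sd <- sqrt(rowSums((Tm - t_mean)^2) / (ncol(Tm) - 1))
  p_sum <- rowSums(Pm)
  p_mean <- p_sum / 12
  p_sd <- sqrt(rowSums((Pm - p_mean)^2) / (ncol(Pm) - 1))
  psd <- ifelse(p_mean > 0, p_sd / p_mean, 0)
  psd[is.na(p_mean)] <- NA_real_

  out <- list(
    tm  = t_mean,
    twm = do.call(pmax, asplit(Tm, 2)),
    tcm = do.call(pmin, asplit(Tm, 2)),
    tsd = t_sd,
    pm  = p_sum,
    pwm = do.call(pmax, asplit(Pm, 2)),
    pdm = do.call(pmin, asplit(Pm, 2)),
    psd = psd
  )
  # a cell nodata in any month (of either variable) is nodata everywhere
  bad <- is.na(t_mean) | is.na(p_sum)
  lapply(out, function(v) { v[bad] <- NA_real_; rg_like(tmpl, v) })
}

#' Growing degree days from monthly mean temperatures
#'
#' Monthly approximation: `sum_m max(0, t_m - base_temp) * days_m`.
#' Base temperature defaults to 5 degC, the standard threshold for
#' temperate tree growth.
#'
#' @param monthly_t list of 12 `raster_grid`s (degC).
#' @param base_temp base temperature (degC); must be finite.
#' @param days_per_month 12 month lengths (default calendar, no leap).
#' @return `raster_grid` of degC-days (>= 0).
#' @export
growing_degree_days <- function(monthly_t, base_temp = 5,
                                days_per_month = c(31, 28, 31, 30, 31, 30,
                                                   31, 31, 30, 31, 30, 31)) {
  if (!is.finite(base_temp)) stop("base_temp must be finite")
  if (length(days_per_month) != 12) stop("need 12 month lengths")
  Tm <- month_matrix(monthly_t)
  gdd <- as.vector(pmax(Tm - base_temp, 0) %*% days_per_month)
  rg_like(monthly_t[[1]], gdd)
}

# Thornthwaite annual potential evapotranspiration (mm) from monthly
# mean temperatures; standard 30-day/12-hour form without daylength
# correction. Months at or below 0 degC contribute nothing.
thornthwaite_pet <- function(Tm) {
  Tpos <- pmax(Tm, 0)
  I <- rowSums((Tpos / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- 16 * (10 * Tpos / ifelse(I > 0, I, NA))^a
  pet[Tpos == 0] <- 0
  ann <- rowSums(pet)
  ann[I == 0] <- 0  # all months frozen
  ann
}

#' Moisture index: annual precipitation over potential evapotranspiration
#'
#' `mi = pm / PET`, with PET the Thornthwaite annual potential
#' evapotranspiration computed from the monthly temperatures. Cells
#' where PET is 0 (every month at or below 0 degC) are assigned the
#' ceiling value; all values are capped at the ceiling.
#'
#' @param monthly_t,monthly_p lists of 12 aligned `raster_grid`s.
#' @param ceiling cap for the (dimensionless) index, default 10.
#' @return `raster_grid`.
#' @export
moisture_index <- function(monthly_t, monthly_p, ceiling = 10) {
  Tm <- month_matrix(monthly_t)
  Pm <- month_matrix(monthly_p)
  rg_check_aligned(c(monthly_t[1], monthly_p[1]))
  pet <- thornthwaite_pet(Tm)
  pm <- rowSums(Pm)
  mi <- ifelse(pet > 0, pmin(pm / pet, ceiling), ceiling)
  mi[is.na(pm) | is.na(pet)] <- NA_real_
  rg_like(monthly_t[[1]], mi)
}

#' Full ten-variable bioclim stack for a landscape
#'
#' Convenience wrapper: the eight [derive_bioclim()] variables plus
#' `gdd` ([growing_degree_days()]) and `mi` ([moisture_index()]).
#'
#' @param landscape a `landscape`, or a list with `monthly_t`/`monthly_p`.
#' @param base_temp,mi_ceiling passed to the respective derivations.
#' @return named list of ten `raster_grid`s
#'   (tm, twm, tcm, tsd, pm, pwm, pdm, psd, gdd, mi).
#' @export
bioclim_stack <- function(landscape, base_temp = 5, mi_ceiling = 10) {
  out <- derive_bioclim(landscape$monthly_t, landscape$monthly_p)
  out$gdd <- growing_degree_days(landscape$monthly_t, base_temp)
  out$mi <- moisture_index(landscape$monthly_t, landscape$monthly_p, mi_ceiling)
  out
}

# bilinear interpolation of a coarse grid at the fine template's cell
# centers, anchored at coarse cell centers; outside the center hull the
# edge value is held (nearest extrapolation)
interp_coarse_to_fine <- function(coarse, template) {
  cv <- coarse$values
  if (nrow(cv) < 2 || ncol(cv) < 2) stop("coarse grid must be at least 2x2")
  # coarse cell-center coordinates, increasing order for interp2
  xc <- coarse$xmin + (seq_len(ncol(cv)) - 0.5) * coarse$res
  yc_desc <- coarse$ymax - (seq_len(nrow(cv)) - 0.5) * coarse$res  # north->south
  yc <- rev(yc_desc)
  Z <- cv[nrow(cv):1, , drop = FALSE]

  nr <- nrow(template$values); ncf <- ncol(template$values)
  ctr <- cell_centers(template,
                      rows = rep(seq_len(nr), times = ncf),
                      cols = rep(seq_len(ncf), each = nr))
  if (min(ctr$x) < coarse$xmin || max(ctr$x) > coarse$xmin + ncol(cv) * coarse$res ||
      min(ctr$y) < coarse$ymax - nrow(cv) * coarse$res || max(ctr$y) > coarse$ymax)
    stop("coarse grid does not cover the fine extent")
  xp <- pmin(pmax(ctr$x, xc[1]), xc[length(xc)])
  yp <- pmin(pmax(ctr$y, yc[1]), yc[length(yc)])
  fine <- pracma::interp2(xc, yc, Z, xp, yp, method = "linear")
  rg_like(template, matrix(fine, nr, ncf))
}

#' Downscale a coarse climate anomaly and add it to the baseline
#'
#' Each fine cell's future monthly value is the baseline value plus the
#' bilinear interpolation of the coarse anomaly at the fine cell
#' center (anchored at coarse cell centers; edge values held outside
#' the center hull). Returns a future `landscape` sharing the
#' baseline's elevation and geometry.
#'
#' @param scenario a `scenario_anomaly` from [generate_scenarios()].
#' @param baseline the current `landscape`.
#' @return a `landscape` with future `monthly_t` and `monthly_p`
#'   (precipitation floored at 0).
#' @export
downscale_anomaly <- function(scenario, baseline) {
  ft <- vector("list", 12); fp <- vector("list", 12)
  for (m in 1:12) {
    dT <- interp_coarse_to_fine(scenario$coarse_dT[[m]], baseline$elevation)
    dP <- interp_coarse_to_fine(scenario$coarse_dP[[m]], baseline$elevation)
    ft[[m]] <- rg_like(baseline$elevation,
                       baseline$monthly_t[[m]]$values + dT$values)
    fp[[m]] <- rg_like(baseline$elevation,
                       pmax(0, baseline$monthly_p[[m]]$values + dP$values))
  }
  out <- baseline
  out$monthly_t <- ft
  out$monthly_p <- fp
  out$scenario_id <- scenario$id
  out
}
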
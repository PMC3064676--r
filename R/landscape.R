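# Deterministic seed derivation: every stochastic stage of the pipeline
# draws its own child seed from the master seed so that stages can be
# re-run in isolation. Kept below 2^31 (R integers are 32-bit).
child_seed <- function(seed, k) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 16807
  as.integer(x %% 2147483647)
}

# Spatially correlated "value noise": iid normals on a coarse lattice,
# bilinearly interpolated to the fine grid. scale_cells controls the
# correlation length in fine-grid cells.
value_noise <- function(nr, nc, scale_cells, sd, seed) {
  if (sd == 0) return(matrix(0, nr, nc))
  set.seed(seed)
  ncr <- max(2L, ceiling(nr / scale_cells) + 1L)
  ncc <- max(2L, ceiling(nc / scale_cells) + 1L)
  coarse <- matrix(stats::rnorm(ncr * ncc, sd = sd), ncr, ncc)
  # coarse lattice positioned so its nodes span [1, nr] x [1, nc]
  yc <- seq(1, nr, length.out = ncr)
  xc <- seq(1, nc, length.out = ncc)
  fine <- pracma::interp2(xc, yc, coarse,
                          rep(seq_len(nc), each = nr),
                          rep(seq_len(nr), times = nc),
                          method = "linear")
  matrix(fine, nr, nc)
}

#' Default relief and climate parameters for the island simulator
#'
#' The defaults emulate a mountainous Mediterranean island: a single
#' massif rising to 2700 m, a coastal monthly climatology with hot dry
#' summers and mild wet winters, a 6.5 degC/km lapse rate, and
#' orographically enhanced precipitation.
#'
#' @return named lists of parameters accepted by [generate_island()].
#' @export
default_relief_params <- function() {
  list(
    summit = 2700,          # m, highest peak
    radius_frac = 0.85,     # island radius as fraction of half-extent
    shape_exp = 1.3,        # radial profile exponent
    noise_amp = 0.35,       # relative relief roughness
    noise_scale = 20        # correlation length (cells)
  )
}

#' @rdname default_relief_params
#' @export
default_climate_params <- function() {
  list(
    lapse_rate = 6.5 / 1000,  # degC per m
    sea_level_t = c(9, 9.5, 11, 13.5, 17.5, 21, 24, 24.5, 21.5, 17.5, 13, 10),
    sea_level_p = c(75, 65, 60, 55, 45, 20, 10, 20, 45, 85, 95, 85),  # mm/month
    oro_factor = 0.9,         # relative precip increase per km elevation
    t_noise_sd = 0.3,         # degC, spatially correlated
    p_noise_sd = 5,           # mm, spatially correlated
    noise_scale = 16          # correlation length (cells)
  )
}

#' Generate a synthetic mountainous island with monthly climate
#'
#' Builds an island landscape on a regular grid: elevation is a radial
#' dome perturbed by correlated noise (cells at or below sea level are
#' nodata), monthly temperature is the sea-level climatology minus
#' `lapse_rate * elevation` plus correlated noise, and monthly
#' precipitation increases with elevation by the orographic factor.
#' Deterministic for a fixed seed.
#'
#' @param grid_size integer pair (rows, cols), each >= 32.
#' @param seed integer seed.
#' @param relief_params see [default_relief_params()].
#' @param climate_params see [default_climate_params()]; `lapse_rate`
#'   must be non-negative (0 gives spatially flat temperatures when the
#'   noise sd is also 0).
#' @param res cell size in km.
#' @return an object of class `landscape`: `elevation` (m,
#'   `raster_grid`), `monthly_t` and `monthly_p` (lists of 12
#'   `raster_grid`s, degC and mm), `pixel_area_km2`.
#' @export
generate_island <- function(grid_size = c(128, 128), seed = 1,
                            relief_params = default_relief_params(),
                            climate_params = default_climate_params(),
                            res = 1) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 2 || any(grid_size < 32))
    stop("grid_size must be two integers >= 32")
  if (is.null(climate_params$lapse_rate) || climate_params$lapse_rate < 0)
    stop("lapse_rate must be non-negative")
  nr <- grid_size[1]; nc <- grid_size[2]

  rp <- utils::modifyList(default_relief_params(), relief_params)
  cp <- utils::modifyList(default_climate_params(), climate_params)

  # radial dome + multiplicative roughness
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt(((rows - (nr + 1) / 2) / (nr / 2))^2 +
              ((cols - (nc + 1) / 2) / (nc / 2))^2)
  base <- 1 - (d / rp$radius_frac)^rp$shape_exp
  rough <- value_noise(nr, nc, rp$noise_scale, rp$noise_amp,
                       child_seed(seed, 11))
  elev <- base * (1 + rough)
  elev[elev <= 0] <- NA_real_                    # sea
  elev <- elev / max(elev, na.rm = TRUE) * rp$summit
  elevation <- raster_grid(elev, xmin = 0, ymax = nr * res, res = res)

  monthly_t <- vector("list", 12)
  monthly_p <- vector("list", 12)
  for (m in 1:12) {
    tn <- value_noise(nr, nc, cp$noise_scale, cp$t_noise_sd,
                      child_seed(seed, 100 + m))
    pn <- value_noise(nr, nc, cp$noise_scale, cp$p_noise_sd,
                      child_seed(seed, 200 + m))
    tv <- cp$sea_level_t[m] - cp$lapse_rate * elev + tn
    pv <- pmax(0, cp$sea_level_p[m] * (1 + cp$oro_factor * elev / 1000) + pn)
    tv[is.na(elev)] <- NA_real_
    pv[is.na(elev)] <- NA_real_
    monthly_t[[m]] <- rg_like(elevation, tv)
    monthly_p[[m]] <- rg_like(elevation, pv)
  }

  structure(
    list(elevation = elevation, monthly_t = monthly_t, monthly_p = monthly_p,
         pixel_area_km2 = res^2, relief_params = rp, climate_params = cp,
         seed = seed),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  e <- x$elevation$values
  land <- sum(is.finite(e))
  cat(sprintf(
    "<landscape> %d x %d cells (%d land, %d sea), summit %.0f m, %.3g km2/cell\n",
    nrow(e), ncol(e), land, sum(!is.finite(e)), max(e, na.rm = TRUE),
    x$pixel_area_km2))
  invisible(x)
}

# land (non-sea) mask as a logical matrix
land_mask <- function(landscape) is.finite(landscape$elevation$values)
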
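# product of independent Gaussian responses over named bioclim
# variables, max-normalized to [0,1] over land
niche_suitability <- function(bioclim, niche) {
  vars <- names(niche)
  missing <- setdiff(vars, names(bioclim))
  if (length(missing))
    stop("niche variables not derivable: ", paste(missing, collapse = ", "))
  tmpl <- bioclim[[vars[1]]]
  suit <- rep(1, length(tmpl$values))
  for (v in vars) {
    p <- niche[[v]]
    if (is.null(p$opt) || is.null(p$sd) || p$sd <= 0)
      stop("each niche entry needs opt and sd > 0")
    suit <- suit * exp(-((as.vector(bioclim[[v]]$values) - p$opt)^2) /
                         (2 * p$sd^2))
  }
  mx <- max(suit, na.rm = TRUE)
  if (mx > 0) suit <- suit / mx
  rg_like(tmpl, suit)
}

new_truth <- function(fundamental_suitability, fundamental_range,
                      realized_range, coppice_cells, niche, cutoff, species) {
  structure(
    list(fundamental_suitability = fundamental_suitability,
         fundamental_range = fundamental_range,
         realized_range = realized_range,
         coppice_cells = coppice_cells,
         niche = niche, occupancy_cutoff = cutoff, species = species),
    class = "virtual_species_truth"
  )
}

#' @export
print.virtual_species_truth <- function(x, ...) {
  cat(sprintf(
    "<virtual_species_truth> '%s': fundamental %d cells, realized %d cells, %d coppices\n",
    x$species,
    sum(x$fundamental_range$values == 1, na.rm = TRUE),
    sum(x$realized_range$values == 1, na.rm = TRUE),
    nrow(x$coppice_cells)))
  invisible(x)
}

#' Define a virtual species with a known fundamental niche, truncated
#' by simulated anthropogenic clearing
#'
#' The fundamental suitability is a product of independent Gaussian
#' responses to bioclimatic variables, max-normalized to \[0,1\]. Cells
#' with suitability at or above `occupancy_cutoff` form the fundamental
#' range. Cells of the fundamental range below `truncation_elevation`
#' are removed from the realized range independently with probability
#' `clearing_fraction` (emulating historical removal of lowland stands
#' by human land use). `n_coppices` relict cells are then sampled
#' uniformly from the cleared part (fundamental minus realized) — the
#' surviving evidence that the species tolerates the lowland climate.
#'
#' @param landscape a `landscape`.
#' @param niche named list over bioclim variable names, each a
#'   `list(opt =, sd =)` Gaussian response.
#' @param truncation_elevation clearing applies below this elevation (m).
#' @param clearing_fraction per-cell removal probability in \[0,1\].
#' @param n_coppices number of relict cells to mark.
#' @param occupancy_cutoff suitability cutoff defining the fundamental
#'   range (default 0.5).
#' @param seed integer seed; output is deterministic per seed.
#' @param species species label.
#' @return a `virtual_species_truth`.
#' @export
define_virtual_species <- function(landscape, niche,
                                   truncation_elevation = 1000,
                                   clearing_fraction = 0.95,
                                   n_coppices = 20,
                                   occupancy_cutoff = 0.5,
                                   seed = 1, species = "species") {
  if (clearing_fraction < 0 || clearing_fraction > 1)
    stop("clearing_fraction must be in [0, 1]")
  bc <- bioclim_stack(landscape)
  suit <- niche_suitability(bc, niche)
  fund <- rg_like(suit, as.numeric(suit$values >= occupancy_cutoff))

  elev <- landscape$elevation$values
  realized_v <- fund$values
  lowland <- which(fund$values == 1 & elev < truncation_elevation)
  if (length(lowland) && clearing_fraction > 0) {
    set.seed(child_seed(seed, 1))
    cleared <- lowland[stats::runif(length(lowland)) < clearing_fraction]
    realized_v[cleared] <- 0
  }
  realized <- rg_like(fund, realized_v)

  truncated <- which(fund$values == 1 & realized_v == 0)
  if (n_coppices > length(truncated))
    stop(sprintf(
      "requested %d coppices but only %d truncated cells available (short by %d)",
      n_coppices, length(truncated), n_coppices - length(truncated)))
  coppice_idx <- integer(0)
  if (n_coppices > 0) {
    set.seed(child_seed(seed, 2))
    coppice_idx <- sort(truncated[sample.int(length(truncated), n_coppices)])
  }
  nr <- nrow(fund$values)
  cop <- data.frame(row = ((coppice_idx - 1) %% nr) + 1L,
                    col = ((coppice_idx - 1) %/% nr) + 1L)
  cop <- cbind(cop, cell_centers(fund, cop$row, cop$col))

  new_truth(suit, fund, realized, cop, niche, occupancy_cutoff, species)
}

#' Sample presence points (and emit coppice records) for a virtual species
#'
#' Each occupied (realized-range) cell is detected independently with
#' probability `detection_prob`; `n_presence` detected cells are then
#' sampled without replacement and reported at their cell centers.
#' Coppice cells are appended as `role = "coppice"` records (they never
#' enter model fitting; they only inform the coppice threshold).
#'
#' @param truth a `virtual_species_truth` with a non-empty realized range.
#' @param n_presence number of presence points.
#' @param detection_prob per-cell detection probability.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`, `species`, `role`.
#' @export
sample_occurrences <- function(truth, n_presence, detection_prob = 1,
                               seed = 1) {
  occ_cells <- which(truth$realized_range$values == 1)
  if (!length(occ_cells)) stop("realized range is empty")
  set.seed(child_seed(seed, 3))
  if (detection_prob < 1) {
    occ_cells <- occ_cells[stats::runif(length(occ_cells)) < detection_prob]
  }
  if (n_presence > length(occ_cells))
    stop(sprintf("n_presence (%d) exceeds detectable occupied cells (%d)",
                 n_presence, length(occ_cells)))
  picked <- sort(occ_cells[sample.int(length(occ_cells), n_presence)])
  nr <- nrow(truth$realized_range$values)
  rows <- ((picked - 1) %% nr) + 1L
  cols <- ((picked - 1) %/% nr) + 1L
  ctr <- cell_centers(truth$realized_range, rows, cols)
  pres <- data.frame(x = ctr$x, y = ctr$y, species = truth$species,
                     role = "presence", stringsAsFactors = FALSE)
  if (nrow(truth$coppice_cells)) {
    pres <- rbind(pres, data.frame(
      x = truth$coppice_cells$x, y = truth$coppice_cells$y,
      species = truth$species, role = "coppice", stringsAsFactors = FALSE))
  }
  pres
}

#' Define a bird species obligately dependent on a tree species
#'
#' The bird's fundamental suitability is its (max-normalized) Gaussian
#' climate response multiplied by the indicator that at least one host
#' tree's fundamental range covers the cell; its realized range is the
#' climate range intersected with the union of the trees' realized
#' ranges — so the bird inherits the trees' anthropogenic truncation.
#' With `require_host = FALSE` the indicator is identically 1 and the
#' result equals a pure climate species.
#'
#' @param pine_truths non-empty list of `virtual_species_truth` for the
#'   host trees.
#' @param landscape the shared `landscape`.
#' @param bird_niche Gaussian responses as in [define_virtual_species()].
#' @param occupancy_cutoff suitability cutoff, default 0.5.
#' @param seed integer seed (reserved; generation is deterministic).
#' @param species species label.
#' @param require_host set `FALSE` to drop the host dependence.
#' @return a `virtual_species_truth` (no coppices).
#' @export
generate_bird_truth <- function(pine_truths, landscape, bird_niche,
                                occupancy_cutoff = 0.5, seed = 1,
                                species = "bird", require_host = TRUE) {
  if (!length(pine_truths)) stop("need at least one host tree truth")
  rg_check_aligned(c(list(landscape$elevation),
                     lapply(pine_truths, function(t) t$fundamental_range)))
  bc <- bioclim_stack(landscape)
  climate_suit <- niche_suitability(bc, bird_niche)

  any_fund <- Reduce(`|`, lapply(pine_truths,
                                 function(t) t$fundamental_range$values == 1))
  any_real <- Reduce(`|`, lapply(pine_truths,
                                 function(t) t$realized_range$values == 1))
  if (!require_host) {
    any_fund[] <- TRUE
    any_real[] <- TRUE
  }
  suit_v <- climate_suit$values * as.numeric(any_fund)
  suit_v[is.na(climate_suit$values)] <- NA_real_
  suit <- rg_like(climate_suit, suit_v)
  fund <- rg_like(suit, as.numeric(suit_v >= occupancy_cutoff))
  real <- rg_like(suit, as.numeric(suit_v >= occupancy_cutoff & any_real))

  new_truth(suit, fund, real, data.frame(row = integer(0), col = integer(0),
                                         x = numeric(0), y = numeric(0)),
            bird_niche, occupancy_cutoff, species)
}

#' Default emission-scenario anomaly specifications
#'
#' Three storylines analogous to the IPCC A1/A2/B1 family for a
#' Mediterranean island by 2100: strong, stronger and moderate warming
#' with summer-dominated drying (annual-mean monthly values).
#'
#' @return data.frame with columns `id`, `dT` (degC), `dP` (mm/month).
#' @export
default_scenarios <- function() {
  data.frame(id = c("A1", "A2", "B1"),
             dT = c(3.5, 4.0, 2.5),
             dP = c(-15, -20, -8),
             stringsAsFactors = FALSE)
}

#' Generate coarse future climate anomaly grids per emission scenario
#'
#' Emulates general-circulation-model output delivered at a much
#' coarser resolution than the baseline climate: per scenario, 12
#' monthly temperature and 12 monthly precipitation anomaly grids on a
#' lattice `coarse_factor` times coarser than the landscape, fully
#' covering its extent, spatially smooth around the scenario's stated
#' means.
#'
#' @param landscape the baseline `landscape`.
#' @param scenario_specs data.frame with `id`, `dT`, `dP` (see
#'   [default_scenarios()]); must be non-empty.
#' @param coarse_factor coarse-to-fine resolution ratio, >= 2.
#' @param noise_sd_t,noise_sd_p sd of the per-coarse-cell anomaly noise.
#' @param seed integer seed.
#' @return list of `scenario_anomaly` objects (`id`, `coarse_dT`,
#'   `coarse_dP` as lists of 12 coarse `raster_grid`s).
#' @export
generate_scenarios <- function(landscape, scenario_specs = default_scenarios(),
                               coarse_factor = 8, noise_sd_t = 0.4,
                               noise_sd_p = 4, seed = 1) {
  if (!nrow(scenario_specs)) stop("scenario_specs is empty")
  if (coarse_factor < 2) stop("coarse_factor must be >= 2")
  fine <- landscape$elevation
  cres <- fine$res * coarse_factor
  ncr <- ceiling(nrow(fine$values) / coarse_factor) + 1L
  ncc <- ceiling(ncol(fine$values) / coarse_factor) + 1L
  # centered so the coarse cell-center hull covers the fine extent
  cxmin <- fine$xmin - cres / 2
  cymax <- fine$ymax + cres / 2

  coarse_grid <- function(mean_val, sd, sub_seed) {
    set.seed(sub_seed)
    raster_grid(matrix(stats::rnorm(ncr * ncc, mean_val, sd), ncr, ncc),
                xmin = cxmin, ymax = cymax, res = cres)
  }

  out <- vector("list", nrow(scenario_specs))
  for (i in seq_len(nrow(scenario_specs))) {
    sp <- scenario_specs[i, ]
    dT <- lapply(1:12, function(m)
      coarse_grid(sp$dT, noise_sd_t, child_seed(seed, 1000 * i + m)))
    dP <- lapply(1:12, function(m)
      coarse_grid(sp$dP, noise_sd_p, child_seed(seed, 1000 * i + 100 + m)))
    out[[i]] <- structure(list(id = sp$id, coarse_dT = dT, coarse_dP = dP),
                          class = "scenario_anomaly")
  }
  names(out) <- scenario_specs$id
  out
}
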
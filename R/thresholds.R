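#' Binarization threshold specification
#'
#' @param kind one of `"maxTSS"`, `"LPT"`, `"LPT_coppice"`.
#' @param value numeric cutoff in \[0,1\].
#' @param provenance free-form description of the defining data.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(kind = c("maxTSS", "LPT", "LPT_coppice"),
                           value, provenance = "") {
  kind <- match.arg(kind)
  if (!is.finite(value) || value < 0 || value > 1)
    stop("threshold value must be in [0, 1]")
  structure(list(kind = kind, value = value, provenance = provenance),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s = %.4f (%s)\n", x$kind, x$value,
              x$provenance))
  invisible(x)
}

#' Write a threshold to a JSON sidecar file
#'
#' @param t a `threshold_spec`.
#' @param path output path.
#' @export
write_threshold_json <- function(t, path) {
  jsonlite::write_json(list(kind = t$kind, value = t$value,
                            provenance = t$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Threshold maximizing the True Skill Statistic
#'
#' Scans all candidate thresholds — the sorted unique scores plus the
#' midpoints between consecutive unique scores — and returns the one
#' maximizing [tss()]. Because TSS only changes where a score is
#' crossed, this finite candidate set maximizes exactly. Ties are
#' broken toward the smallest maximizing candidate.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 vector, both classes present.
#' @return a `threshold_spec` of kind `"maxTSS"`.
#' @export
max_tss_threshold <- function(scores, labels) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("maxTSS threshold needs both classes")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) sort(c(u, (u[-1] + u[-length(u)]) / 2)) else u
  # sens(t) and spec(t) for all candidates at once via counts of
  # scores >= t in each class
  s1 <- sort(scores[labels == 1])
  s0 <- sort(scores[labels == 0])
  n_ge <- function(sorted, t) length(sorted) - findInterval(t, sorted,
                                                            left.open = TRUE)
  sens <- n_ge(s1, cand) / length(s1)
  spec <- 1 - n_ge(s0, cand) / length(s0)
  val <- sens + spec - 1
  best <- which(val == max(val))[1]
  threshold_spec("maxTSS", cand[best],
                 sprintf("maxTSS over %d scores", length(scores)))
}

#' Lowest presence threshold (LPT)
#'
#' The smallest suitability that the map assigns to any point of the
#' requested role: with `role = "presence"` the classical LPT (binary
#' maps at this cutoff retain every defining presence); with `role =
#' "coppice"` the coppice-informed variant, resolved on relict points
#' that persist in the anthropogenically cleared zone and therefore
#' reach closer to the fundamental niche.
#'
#' @param map suitability `raster_grid`.
#' @param points occurrence data.frame.
#' @param role `"presence"` or `"coppice"`.
#' @return a `threshold_spec` of kind `"LPT"` or `"LPT_coppice"`.
#' @export
lowest_presence_threshold <- function(map, points,
                                      role = c("presence", "coppice")) {
  role <- match.arg(role)
  pts <- points[points$role == role, , drop = FALSE]
  vals <- extract_at(map, pts$x, pts$y)
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop(sprintf("no '%s' points on valid cells", role))
  threshold_spec(if (role == "presence") "LPT" else "LPT_coppice",
                 min(vals),
                 sprintf("min suitability over %d %s points",
                         length(vals), role))
}

#' Binarize a suitability map at a threshold
#'
#' Cell value 1 where suitability >= the threshold (the >= convention
#' keeps an LPT's own defining points inside the binary range), 0
#' elsewhere; nodata preserved.
#'
#' @param map suitability `raster_grid`.
#' @param t a `threshold_spec` (or bare number).
#' @return binary `raster_grid`.
#' @export
binarize <- function(map, t) {
  v <- if (inherits(t, "threshold_spec")) t$value else t
  rg_like(map, as.numeric(map$values >= v))
}

#' Zero out suitability below a threshold
#'
#' Pixels below the threshold are considered outside the distribution
#' and set to zero suitability; pixels at or above keep their value;
#' nodata preserved.
#'
#' @inheritParams binarize
#' @return filtered `raster_grid`.
#' @export
zero_below <- function(map, t) {
  v <- if (inherits(t, "threshold_spec")) t$value else t
  out <- map$values
  out[is.finite(out) & out < v] <- 0
  rg_like(map, out)
}
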
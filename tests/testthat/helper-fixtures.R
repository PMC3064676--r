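# shared in-code fixtures; everything is generated at test time

# constant-valued raster on a simple unit geotransform
const_grid <- function(value, nr = 6, nc = 6, xmin = 0, ymax = nr, res = 1) {
  raster_grid(matrix(value, nr, nc), xmin = xmin, ymax = ymax, res = res)
}

# 12 monthly grids with the given per-month constants
monthly_const <- function(values, nr = 4, nc = 4) {
  lapply(values, const_grid, nr = nr, nc = nc)
}

# minimal training table from raw vectors
make_table <- function(X, y) {
  X <- as.data.frame(X)
  tab <- cbind(X, response = y, weight = 1, point_id = seq_len(nrow(X)))
  attr(tab, "predictors") <- names(X)
  class(tab) <- c("training_table", "data.frame")
  tab
}

# a linearly separable two-predictor table
separable_table <- function(n = 200, seed = 42) {
  set.seed(seed)
  x <- stats::rnorm(n)
  make_table(data.frame(a = x, b = stats::rnorm(n)), as.integer(x > 0))
}

# small island reused by several files (built once per test run)
tiny_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_island(c(64, 64), seed = 3)
    cache
  }
})

# brute-force all-pairs AUC oracle: P(score1 > score0) + 0.5 P(tie)
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# exhaustive grid-scan oracle for the TSS-maximizing threshold
max_tss_gridscan <- function(scores, labels, grid = seq(0, 1, length.out = 1001)) {
  vals <- vapply(grid, function(t) tss(scores, labels, t), 0)
  max(vals)
}
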
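# Shared fixtures, computed lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# small synthetic world reused by most suites
test_world <- function() {
  memo("world", generate_world(
    sim_config(grid_width = 60, grid_height = 60, n_sites = 300, seed = 42)))
}

test_matrix <- function() {
  memo("matrix", {
    w <- test_world()
    extract_at_points(w$covariates, w$samples)
  })
}

# predictor matrix + response in the lightweight plain-matrix form
as_cm <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  attr(x, "response") <- y
  x
}

# regression task with known informative set: 3 signal + `p_noise` pure-noise
# standard-normal predictors
selection_task <- function(n = 400, p_noise = 20, seed = 1) {
  set.seed(seed)
  p <- 3 + p_noise
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, c(paste0("inf", 1:3),
                                      paste0("noise", seq_len(p_noise)))))
  y <- 1.0 * x[, 1] + 0.8 * x[, 2] + 0.6 * x[, 3] + rnorm(n, 0, 0.5)
  as_cm(x, y)
}

# constant raster helper
const_raster <- function(value, n = 10, cell_km = 1, lon0 = 99, lat0 = 49) {
  raster_grid(matrix(value, n, n), xmin = lon0, ymax = lat0,
              dx = cell_km / 110.574)
}

# sm2-schema CSV fixture written to a temp file
write_sm2_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}
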
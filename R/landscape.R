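# Gridded landscapes, climate scenarios, per-cell optima through time, and
# seed dispersal between cells.
#
# Grids are row-major and north-up: layer matrices have one row per grid
# row (row 1 = northern edge) and cells are indexed 1-based as
# cell = (row - 1) * ncols + col.

#' Construct a gridded landscape
#'
#' Holds the static carbonate layer and the baseline (pre-forcing)
#' temperature and precipitation layers of one study grid, together with
#' the standardisation used to express optima and trait values on a
#' common scale.  The constructor initialises it to z-scores over the
#' baseline landscape; [init_state()] replaces it with niche-width units
#' (z-scores over the predicted-occupied cells) when a simulation is set
#' up.  Raw units are retained for input/output.
#'
#' @param temperature,precipitation,carbonate Numeric matrices of equal
#'   dimension (rows x cols, row 1 = north): mean annual temperature (deg C),
#'   annual precipitation (mm), percent carbonate bedrock.
#' @param cell_size Cell edge length in metres (default 250).
#' @return An object of class `eer_landscape`.
#' @export
landscape <- function(temperature, precipitation, carbonate,
                      cell_size = 250) {
  dims <- dim(temperature)
  if (!identical(dims, dim(precipitation)) ||
      !identical(dims, dim(carbonate)))
    stop("all layers must share the same grid dimensions")
  env <- cbind(temperature = as.vector(t(temperature)),
               precipitation = as.vector(t(precipitation)),
               carbonate = as.vector(t(carbonate)))
  scaling <- list(center = colMeans(env), sd = apply(env, 2, stats::sd))
  bad <- is.na(scaling$sd) | scaling$sd == 0
  scaling$sd[bad] <- 1
  structure(list(nrows = dims[1], ncols = dims[2], cell_size = cell_size,
                 env = env, scaling = scaling),
            class = "eer_landscape")
}

#' @export
print.eer_landscape <- function(x, ...) {
  cat(sprintf("Landscape: %d x %d cells of %g m (%.3g km^2)\n",
              x$nrows, x$ncols, x$cell_size, grid_area(x)))
  rng <- apply(x$env, 2, range)
  cat(sprintf("  temperature %.2f..%.2f degC, precipitation %.0f..%.0f mm, carbonate %.0f..%.0f%%\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

n_cells <- function(ls) ls$nrows * ls$ncols

cell_row <- function(ls, cell) (cell - 1L) %/% ls$ncols + 1L
cell_col <- function(ls, cell) (cell - 1L) %% ls$ncols + 1L

#' Total grid area
#'
#' @param ls An `eer_landscape`.
#' @return Area in square kilometres (`rows * cols * cell_size^2 / 1e6`).
#' @export
grid_area <- function(ls) n_cells(ls) * ls$cell_size^2 / 1e6

# standardize a raw env matrix (ncell x 3) to landscape z-scores
scale_env <- function(ls, env)
  sweep(sweep(env, 2, ls$scaling$center), 2, ls$scaling$sd, "/")

#' Climate-change scenario as decadal anchors
#'
#' Per-cell temperature and precipitation values at the decadal anchor
#' years 2010-2090.  Between anchors, values are interpolated linearly in
#' time; before 2010 they are held at the 2010 values and after 2090 at the
#' 2090 values (the climate remains constant after 2090).
#'
#' @param name Scenario label.
#' @param temperature,precipitation Matrices of ncell rows and one column
#'   per anchor year, in raw units.
#' @param anchor_years Anchor years (default `seq(2010, 2090, 10)`).
#' @return An object of class `eer_scenario`.
#' @export
climate_scenario <- function(name, temperature, precipitation,
                             anchor_years = seq(2010, 2090, 10)) {
  if (ncol(temperature) != length(anchor_years) ||
      ncol(precipitation) != length(anchor_years))
    stop("one column per anchor year required")
  if (nrow(temperature) != nrow(precipitation))
    stop("temperature and precipitation must cover the same cells")
  structure(list(name = name, anchor_years = anchor_years,
                 temperature = temperature, precipitation = precipitation),
            class = "eer_scenario")
}

#' Per-cell environmental optima at a given year
#'
#' Returns the vector of optimal phenotypes `theta` for every cell:
#' (temperature, precipitation, carbonate) under the scenario at `year`,
#' with annual values linearly interpolated between the decadal anchors,
#' clamped to the 2010 anchors before 2010 and to the 2090 anchors after
#' 2090.  Carbonate is static.
#'
#' @param ls An `eer_landscape`.
#' @param scenario An `eer_scenario` covering the same cells.
#' @param year Calendar year in \[2000, 2150\].
#' @param scaled If `TRUE` (default) return landscape z-scores (the trait
#'   scale); otherwise raw units.
#' @return An ncell x 3 matrix with columns temperature, precipitation,
#'   carbonate.
#' @export
theta_at <- function(ls, scenario, year, scaled = TRUE) {
  if (year < 2000 || year > 2150)
    stop("year must lie in [2000, 2150]")
  if (nrow(scenario$temperature) != n_cells(ls))
    stop("scenario does not match the landscape grid")
  ay <- scenario$anchor_years
  y <- min(max(year, ay[1]), ay[length(ay)])
  k <- findInterval(y, ay)
  if (k == length(ay)) {
    tmp <- scenario$temperature[, k]
    prc <- scenario$precipitation[, k]
  } else {
    w <- (y - ay[k]) / (ay[k + 1] - ay[k])
    tmp <- (1 - w) * scenario$temperature[, k] +
      w * scenario$temperature[, k + 1]
    prc <- (1 - w) * scenario$precipitation[, k] +
      w * scenario$precipitation[, k + 1]
  }
  env <- cbind(temperature = tmp, precipitation = prc,
               carbonate = ls$env[, "carbonate"])
  if (scaled) scale_env(ls, env) else env
}

#' Disperse seeds between cells
#'
#' Each seed independently stays in its natal cell with probability
#' `1 - disperse_frac`; otherwise it moves from the natal cell centre by a
#' distance drawn from a negative-exponential kernel with mean
#' `disperse_mean` metres in a uniformly random direction.  Seeds landing
#' outside the grid are lost (absorbing boundary).
#'
#' @param cells Integer vector of natal cell indices.
#' @param ls An `eer_landscape`.
#' @param disperse_frac Probability a seed disperses.
#' @param disperse_mean Mean kernel distance (m).
#' @return Integer vector of landing cells, `NA` for seeds lost off-grid.
#' @export
disperse_seeds <- function(cells, ls, disperse_frac, disperse_mean) {
  n <- length(cells)
  out <- cells
  if (n == 0L || disperse_frac <= 0) return(out)
  moves <- stats::runif(n) < disperse_frac
  nm <- sum(moves)
  if (nm == 0L) return(out)
  cs <- ls$cell_size
  r <- stats::rexp(nm, rate = 1 / disperse_mean)
  ang <- stats::runif(nm, 0, 2 * pi)
  x0 <- (cell_col(ls, cells[moves]) - 0.5) * cs
  y0 <- (cell_row(ls, cells[moves]) - 0.5) * cs
  x1 <- x0 + r * cos(ang)
  y1 <- y0 + r * sin(ang)
  col1 <- floor(x1 / cs) + 1
  row1 <- floor(y1 / cs) + 1
  ok <- col1 >= 1 & col1 <= ls$ncols & row1 >= 1 & row1 <= ls$nrows
  dest <- rep(NA_integer_, nm)
  dest[ok] <- as.integer((row1[ok] - 1) * ls$ncols + col1[ok])
  out[moves] <- dest
  out
}

#' Read and write plain-text gridded rasters (ESRI ASCII grid dialect)
#'
#' The header lines are `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize` and `NODATA_value`, followed by `nrows` whitespace-separated
#' data rows from north to south.
#'
#' @param mat Numeric matrix (row 1 = north).
#' @param path File path.
#' @param cell_size Cell size in metres.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel value.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a list with elements `data` (matrix), `cell_size`, `xll`,
#'   `yll`, `nodata`.
#' @export
write_ascii_grid <- function(mat, path, cell_size = 250, xll = 0, yll = 0,
                             nodata = -9999) {
  m <- mat
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cell_size),
    paste("NODATA_value", nodata)), con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(data = m, cell_size = hdr$cellsize, xll = hdr$xllcorner,
       yll = hdr$yllcorner, nodata = hdr$nodata_value)
}

#' Extract a landscape layer as a matrix
#'
#' @param ls An `eer_landscape`.
#' @param which One of `"temperature"`, `"precipitation"`, `"carbonate"`.
#' @return Matrix (rows x cols, row 1 = north).
#' @export
landscape_layer <- function(ls, which = c("temperature", "precipitation",
                                          "carbonate")) {
  which <- match.arg(which)
  matrix(ls$env[, which], nrow = ls$nrows, ncol = ls$ncols, byrow = TRUE)
}
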
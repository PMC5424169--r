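# Synthetic-data generator: alpine-like landscapes on a regular grid,
# decadal warming scenarios of graded severity, pseudo-niche-model
# suitability predictions with controllable skill, and an end-to-end
# micro-study that exercises the whole pipeline at desk scale.
#
# All outputs are pure functions of (spec, seed).

#' Fixture specification
#'
#' Parameters of the synthetic study system.  The defaults emulate a
#' 32 x 32-cell, 250-m grid (64 km^2) on a montane-to-alpine elevation
#' ramp: temperature falls with elevation at a standard lapse rate,
#' precipitation rises with elevation, and carbonate bedrock forms
#' contiguous patches.  Warming severities bracket mild-to-severe forcing
#' pathways (total 2010-2090 warming of about 1.4, 2.6 and 4.0 deg C).
#'
#' @param grid_shape Rows x cols (default `c(32, 32)`).
#' @param cell_size Cell edge (m), default 250.
#' @param elev_range Elevation ramp end points (m).
#' @param lapse Temperature lapse rate (deg C per km of elevation).
#' @param temp_at_base Mean annual temperature (deg C) at the low end of
#'   the ramp.
#' @param precip_base Annual precipitation (mm) at the low end.
#' @param precip_per_m Precipitation increase per m of elevation (mm/m).
#' @param carbonate_frac Fraction of cells on carbonate bedrock.
#' @param warming_per_decade Named vector of per-decade warming (deg C)
#'   for the `mild`, `moderate` and `severe` scenarios (`none` = 0 is
#'   always available).
#' @param precip_trend_per_decade Named vector of per-decade precipitation
#'   trends (mm) for the same severities.
#' @param niche_elev_frac Fraction of the elevation ramp at which the
#'   synthetic species' niche is centred.
#' @param niche_width Length-3 niche widths (deg C, mm, % carbonate) for
#'   the logistic suitability surface.
#' @return An object of class `eer_fixture_spec`.
#' @export
fixture_spec <- function(grid_shape = c(32L, 32L), cell_size = 250,
                         elev_range = c(800, 2000), lapse = 6,
                         temp_at_base = 6, precip_base = 1200,
                         precip_per_m = 0.5, carbonate_frac = 0.5,
                         warming_per_decade = c(mild = 0.18,
                                                moderate = 0.33,
                                                severe = 0.5),
                         precip_trend_per_decade = c(mild = -4,
                                                     moderate = -8,
                                                     severe = -15),
                         niche_elev_frac = 0.6,
                         niche_width = c(2.0, 400, 150)) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 4),
            elev_range[2] > elev_range[1], lapse > 0,
            carbonate_frac > 0, carbonate_frac < 1,
            all(warming_per_decade >= 0))
  structure(list(grid_shape = as.integer(grid_shape),
                 cell_size = cell_size, elev_range = elev_range,
                 lapse = lapse, temp_at_base = temp_at_base,
                 precip_base = precip_base, precip_per_m = precip_per_m,
                 carbonate_frac = carbonate_frac,
                 warming_per_decade = warming_per_decade,
                 precip_trend_per_decade = precip_trend_per_decade,
                 niche_elev_frac = niche_elev_frac,
                 niche_width = niche_width),
            class = "eer_fixture_spec")
}

# smooth random field: superposition of Gaussian bumps
smooth_field <- function(nr, nc, n_bumps = 6, amp = 1, width_frac = 0.25) {
  f <- matrix(0, nr, nc)
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (b in seq_len(n_bumps)) {
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    w <- stats::runif(1, 0.5, 1.5) * width_frac * max(nr, nc)
    a <- stats::rnorm(1, 0, amp)
    f <- f + a * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * w^2))
  }
  f
}

#' Generate a synthetic landscape
#'
#' Elevation is a north-to-south ramp (row 1 = low edge) plus smooth
#' bumps; temperature follows the lapse rate with small local noise,
#' precipitation increases with elevation, and carbonate bedrock is a
#' thresholded smooth field covering `carbonate_frac` of cells (values 0
#' or 100%).
#'
#' @param spec An [fixture_spec()].
#' @param seed RNG seed (all outputs are reproducible from it).
#' @return An `eer_landscape` with attribute `"elevation"` (matrix).
#' @export
make_landscape <- function(spec, seed = 1L) {
  set.seed(seed)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  ramp <- matrix(rep(seq(spec$elev_range[1], spec$elev_range[2],
                         length.out = nr), nc), nr, nc)
  elev <- ramp + smooth_field(nr, nc, amp = 60) +
    matrix(stats::rnorm(nr * nc, 0, 15), nr, nc)
  temp <- spec$temp_at_base -
    spec$lapse * (elev - spec$elev_range[1]) / 1000 +
    matrix(stats::rnorm(nr * nc, 0, 0.08), nr, nc)
  precip <- spec$precip_base +
    spec$precip_per_m * (elev - spec$elev_range[1]) +
    smooth_field(nr, nc, amp = 40) +
    matrix(stats::rnorm(nr * nc, 0, 10), nr, nc)
  carb_field <- smooth_field(nr, nc, n_bumps = 8, amp = 1)
  thr <- stats::quantile(carb_field, 1 - spec$carbonate_frac)
  carb <- ifelse(carb_field >= thr, 100, 0)
  ls <- landscape(temp, precip, carb, cell_size = spec$cell_size)
  attr(ls, "elevation") <- elev
  ls
}

#' Generate a decadal warming scenario
#'
#' Builds decadal climate anchors 2010-2090 for the landscape: uniform
#' per-decade warming (and precipitation trend) of the chosen severity
#' applied to the baseline layers.  Severities order mild < moderate <
#' severe in total 2090 warming; `none` leaves all anchors at the 2010
#' values.
#'
#' @param spec An [fixture_spec()].
#' @param severity One of `"none"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param ls The `eer_landscape` the scenario drives.
#' @return An `eer_scenario`.
#' @export
make_scenario <- function(spec, severity = c("moderate", "none", "mild",
                                             "severe"), ls) {
  severity <- match.arg(severity)
  w <- if (severity == "none") 0 else spec$warming_per_decade[[severity]]
  pt <- if (severity == "none") 0 else
    spec$precip_trend_per_decade[[severity]]
  anchors <- seq(2010, 2090, 10)
  steps <- seq_along(anchors) - 1
  temp <- outer(ls$env[, "temperature"], steps * w, "+")
  precip <- outer(ls$env[, "precipitation"], steps * pt, "+")
  climate_scenario(severity, temp, precip, anchors)
}

#' Niche description of the synthetic species
#'
#' Deterministic function of the fixture spec: the niche is centred at the
#' temperature and precipitation of the `niche_elev_frac` point of the
#' elevation ramp and on carbonate bedrock, with the spec's niche widths.
#'
#' @param spec An [fixture_spec()].
#' @return An [niche_spec()] object.
#' @export
fixture_niche <- function(spec) {
  dz <- spec$niche_elev_frac * diff(spec$elev_range)
  niche_spec(center = c(spec$temp_at_base - spec$lapse * dz / 1000,
                        spec$precip_base + spec$precip_per_m * dz,
                        100),
             width = spec$niche_width)
}

#' Generate pseudo-niche-model predictions
#'
#' Truth presence derives from the logistic suitability response to the
#' baseline environment (`suitability >= 0.5`).  Each pseudo-model
#' distorts the truth probability on the logit scale, `plogis(skill *
#' qlogis(p) + noise)`, so that realised TSS spans a target range; a
#' near-zero skill entry yields a model with TSS below the 0.3 discard
#' threshold.
#'
#' @param ls An `eer_landscape`.
#' @param niche An [niche_spec()].
#' @param skill Per-model logit shrinkage factors in \[0, 1\].
#' @param noise Per-model logit noise standard deviations (recycled).
#' @param seed RNG seed.
#' @return List with `predictions` (list of per-cell probability vectors),
#'   `truth` (logical mask) and `prob_true`.
#' @export
make_predictions <- function(ls, niche, skill = c(1, 0.8, 0.6, 0),
                             noise = 0.5, seed = 1L) {
  set.seed(seed)
  if (length(skill) < 1L) stop("need at least one model")
  noise <- rep_len(noise, length(skill))
  env <- ls$env
  d <- sqrt(rowSums(sweep(sweep(env, 2, niche$center), 2,
                          niche$width, "/")^2))
  prob_true <- 1 / (1 + exp(niche$steepness * (d - niche$edge)))
  truth <- prob_true >= 0.5
  lp <- stats::qlogis(pmin(pmax(prob_true, 1e-6), 1 - 1e-6))
  preds <- lapply(seq_along(skill), function(j)
    stats::plogis(skill[j] * lp + stats::rnorm(length(lp), 0, noise[j])))
  list(predictions = preds, truth = truth, prob_true = prob_true)
}

#' Niche-model presence mask over time
#'
#' The static-model counterpart of the simulator's occupancy: cells whose
#' projected suitability exceeds the presence threshold, per year (the
#' suitability surface is frozen at 2090 afterwards).
#'
#' @param ls,scenario,niche Landscape, scenario, niche description.
#' @param threshold Presence threshold from [binarize_suitability()].
#' @param years Years to evaluate.
#' @return Data frame with `year` and `n_predicted_present`.
#' @export
senm_occupancy <- function(ls, scenario, niche, threshold,
                           years = seq(2010, 2090, 10)) {
  n <- vapply(years, function(y)
    sum(project_suitability(ls, scenario, niche, y) >= threshold),
    numeric(1))
  data.frame(year = years, n_predicted_present = n)
}

#' Run the desk-scale micro-study
#'
#' End-to-end pipeline on synthetic data: build a landscape and warming
#' scenario, generate pseudo-model predictions, ensemble and threshold
#' them, extract the niche width and presence mask, initialise the
#' simulator, burn in, and run replicate climate-forcing simulations
#' 2000-2150.  Defaults use a 16 x 16 grid and a small, fast synthetic
#' species so the full study completes in minutes.
#'
#' @param seed Master seed; replicate streams are drawn from it.
#' @param replicates Scenario-phase replicates started from the shared
#'   burn-in population.
#' @param burn_in_years Burn-in length (years).
#' @param severity Warming severity for [make_scenario()].
#' @param vs_multiplier Selection-variance multiplier on the niche width.
#' @param single_genotype Run the no-evolution global-genotype baseline.
#' @param spec Fixture spec (default 16 x 16 grid).
#' @param sp Species parameters (default the `synthetic` preset).
#' @param gp Genetic parameters (default `genetic_params(mu = 0.001)`).
#' @param n0_adults Founder adults per predicted-occupied cell.
#' @return List with `records` (list of per-replicate record tables),
#'   `senm` (TSS table, threshold, presence mask, niche summary),
#'   `landscape`, `scenario`, `niche`, `species`, `state0` (post-burn-in
#'   state) and `burn_in_diagnostics`.
#' @export
run_micro_study <- function(seed = 1L, replicates = 3L,
                            burn_in_years = 200L, severity = "severe",
                            vs_multiplier = 1, single_genotype = FALSE,
                            spec = fixture_spec(grid_shape = c(16L, 16L)),
                            sp = species_preset("synthetic"),
                            gp = genetic_params(mu = 0.001),
                            n0_adults = 50L) {
  ls <- make_landscape(spec, seed = seed)
  scn <- make_scenario(spec, severity, ls)
  niche <- fixture_niche(spec)
  pp <- make_predictions(ls, niche, seed = seed)
  fits <- lapply(pp$predictions, binarize_suitability, truth = pp$truth)
  scores <- vapply(fits, `[[`, numeric(1), "tss")
  ens <- ensemble_suitability(pp$predictions, scores)
  fit <- binarize_suitability(as.vector(ens), pp$truth)
  ns <- niche_summary(ls$env, fit$mask)   # raw-unit niche summary

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates + 1L)
  state <- init_state(ls, scn, sp, gp, fit$mask,
                      vs_multiplier = vs_multiplier,
                      n0_adults = n0_adults,
                      single_genotype = single_genotype, niche = niche,
                      seed = rep_seeds[1])
  state <- burn_in(state, burn_in_years)
  diag <- attr(state, "diagnostics")

  records <- lapply(seq_len(replicates), function(r) {
    set.seed(rep_seeds[r + 1L])
    run_scenario(state, years = 2000:2150, record_interval = 10)
  })
  list(records = records,
       senm = list(model_tss = scores, threshold = fit$threshold,
                   ensemble_tss = fit$tss, mask = fit$mask,
                   niche_summary = ns),
       landscape = ls, scenario = scn, niche = niche, species = sp,
       genetics = gp, state0 = state, burn_in_diagnostics = diag,
       rep_seeds = rep_seeds)
}

#' Write a ready-to-run input directory of fixture rasters
#'
#' Writes the carbonate layer, the baseline and decadal climate layers and
#' the ensemble suitability/presence rasters as plain-text ASCII grids,
#' plus the TSS table as CSV.
#'
#' @param dir Output directory.
#' @inheritParams run_micro_study
#' @return The directory, invisibly.
#' @export
write_fixture_inputs <- function(dir, spec = fixture_spec(), seed = 1L,
                                 severity = "moderate") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls <- make_landscape(spec, seed = seed)
  scn <- make_scenario(spec, severity, ls)
  niche <- fixture_niche(spec)
  pp <- make_predictions(ls, niche, seed = seed)
  fits <- lapply(pp$predictions, binarize_suitability, truth = pp$truth)
  scores <- vapply(fits, `[[`, numeric(1), "tss")
  ens <- ensemble_suitability(pp$predictions, scores)
  fit <- binarize_suitability(as.vector(ens), pp$truth)
  as_mat <- function(v) matrix(v, ls$nrows, ls$ncols, byrow = TRUE)
  cs <- ls$cell_size
  write_ascii_grid(landscape_layer(ls, "carbonate"),
                   file.path(dir, "carbonate.asc"), cs)
  for (k in seq_along(scn$anchor_years)) {
    y <- scn$anchor_years[k]
    write_ascii_grid(as_mat(scn$temperature[, k]),
                     file.path(dir, sprintf("temperature_%d.asc", y)), cs)
    write_ascii_grid(as_mat(scn$precipitation[, k]),
                     file.path(dir, sprintf("precipitation_%d.asc", y)), cs)
  }
  write_ascii_grid(as_mat(as.vector(ens)),
                   file.path(dir, "suitability.asc"), cs)
  write_ascii_grid(as_mat(as.numeric(fit$mask)),
                   file.path(dir, "presence.asc"), cs)
  utils::write.csv(data.frame(model = seq_along(scores), tss = scores,
                              retained = scores >= 0.3,
                              threshold = fit$threshold),
                   file.path(dir, "tss.csv"), row.names = FALSE)
  invisible(dir)
}
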
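# Output statistics computed from the per-cell census record table
# produced by run_scenario(): occupancy change, adaptive seedling
# survival, population size, Haldane rates of environmental change,
# suitability classes and age structure.

occupied_cells_by_year <- function(records) {
  occ <- records$n_seedling + records$n_pre_adult + records$n_adult > 0
  tapply(occ, records$year, sum)
}

#' Relative occupancy change
#'
#' Per record year, `(cells occupied in year t - cells occupied in the
#' baseline year) / cells occupied in the baseline year`.  A cell counts as
#' occupied when it holds at least one established individual (seedling,
#' pre-adult or adult) at census; banked seeds do not count.
#'
#' @param records Census record table from [run_scenario()].
#' @param baseline_year Baseline (default 2010).
#' @return Data frame with `year` and `occupancy_change`.
#' @export
occupancy_change <- function(records, baseline_year = 2010) {
  occ <- occupied_cells_by_year(records)
  yrs <- as.integer(names(occ))
  if (!baseline_year %in% yrs)
    stop("baseline year not present in the records")
  base <- occ[[as.character(baseline_year)]]
  if (base == 0) stop("zero occupancy in the baseline year")
  data.frame(year = yrs,
             occupancy_change = (as.vector(occ) - base) / base)
}

#' Mean adaptive seedling survival
#'
#' Per record year, the mean over seedlings (at census, i.e. after
#' competition and before selection) of the Gaussian viability survival
#' probability; competition with adults is not part of this quantity.
#' Years without seedlings yield `NA`.
#'
#' @inheritParams occupancy_change
#' @return Data frame with `year` and `adaptive_survival`.
#' @export
adaptive_seedling_survival <- function(records) {
  agg <- function(df) {
    n <- sum(df$n_seedling)
    if (n == 0) return(NA_real_)
    sum(df$mean_fitness * df$n_seedling, na.rm = TRUE) / n
  }
  vals <- vapply(split(records, records$year), agg, numeric(1))
  data.frame(year = as.integer(names(vals)), adaptive_survival = vals,
             row.names = NULL)
}

#' Population size per record year
#'
#' @inheritParams occupancy_change
#' @param stages Which stages to total (default established plants).
#' @return Data frame with `year` and `n`.
#' @export
population_size <- function(records,
                            stages = c("n_seedling", "n_pre_adult",
                                       "n_adult")) {
  tot <- rowSums(records[, stages, drop = FALSE])
  vals <- tapply(tot, records$year, sum)
  data.frame(year = as.integer(names(vals)), n = as.vector(vals))
}

#' Stage structure per record year
#'
#' Relative frequencies of seedlings, pre-adults and adults among
#' established individuals.
#'
#' @inheritParams occupancy_change
#' @return Data frame with `year`, `seedling`, `pre_adult`, `adult`.
#' @export
age_structure <- function(records) {
  agg <- rowsum(records[, c("n_seedling", "n_pre_adult", "n_adult")],
                records$year)
  tot <- rowSums(agg)
  data.frame(year = as.integer(rownames(agg)),
             seedling = agg$n_seedling / tot,
             pre_adult = agg$n_pre_adult / tot,
             adult = agg$n_adult / tot, row.names = NULL)
}

#' Haldane rate of environmental change
#'
#' The per-year change of the local optimum expressed in units of the
#' within-population phenotypic standard deviation of the corresponding
#' trait: `(theta_end - theta_start) / (years * sd_z)`.
#'
#' @param theta_start,theta_end Optimum values at the window ends.
#' @param sd_z Within-population phenotypic standard deviation (> 0).
#' @param years Window length in years (>= 1).
#' @return Haldanes per year (signed).
#' @export
haldane_rate <- function(theta_start, theta_end, sd_z, years) {
  if (any(years < 1)) stop("window must span at least 1 year")
  if (any(sd_z <= 0)) stop("phenotypic standard deviation must be > 0")
  (theta_end - theta_start) / (years * sd_z)
}

#' Mean suitability by occupancy class
#'
#' Per record year, the mean site suitability (probability of presence x
#' 1000) among four cell classes: currently occupied, currently
#' unoccupied, colonised since the baseline year, and extinct since the
#' baseline year.  Classes that are empty in a year yield `NA`.  The
#' suitability column of the records already freezes post-2090 values at
#' the 2090 surface.
#'
#' @inheritParams occupancy_change
#' @return Data frame with `year`, `occupied`, `unoccupied`, `colonized`,
#'   `extinct`.
#' @export
suitability_classes <- function(records, baseline_year = 2010) {
  if (is.null(records$suitability))
    stop("records carry no suitability column (no niche in the state)")
  occ_mat <- records$n_seedling + records$n_pre_adult + records$n_adult > 0
  base <- records[records$year == baseline_year, ]
  if (nrow(base) == 0) stop("baseline year not present in the records")
  occ0 <- logical(max(records$cell))
  occ0[base$cell] <- base$n_seedling + base$n_pre_adult + base$n_adult > 0
  cmean <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  agg <- lapply(split(seq_len(nrow(records)), records$year), function(idx) {
    occ <- occ_mat[idx]
    was <- occ0[records$cell[idx]]
    s <- records$suitability[idx]
    c(occupied = cmean(s[occ]), unoccupied = cmean(s[!occ]),
      colonized = cmean(s[occ & !was]), extinct = cmean(s[!occ & was]))
  })
  out <- do.call(rbind, agg)
  data.frame(year = as.integer(rownames(out)), out, row.names = NULL)
}

#' Mean genetic variance per record year
#'
#' Mean over occupied cells of the per-cell genetic variance, averaged
#' across traits; zero everywhere in single-genotype runs.
#'
#' @inheritParams occupancy_change
#' @return Data frame with `year` and `VG`.
#' @export
genetic_variance <- function(records) {
  gcols <- grep("^g_var_", names(records), value = TRUE)
  vals <- vapply(split(records, records$year), function(df) {
    v <- as.matrix(df[df$occupied, gcols, drop = FALSE])
    if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(year = as.integer(names(vals)), VG = vals, row.names = NULL)
}
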
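# Shared builders for small simulation rigs.

# single-cell landscape with a constant-climate scenario
one_cell_world <- function(temp = 5, precip = 1500, carb = 100) {
  ls <- landscape(matrix(temp), matrix(precip), matrix(carb))
  scn <- climate_scenario("none", matrix(temp, 1, 9), matrix(precip, 1, 9))
  list(ls = ls, scn = scn)
}

# single perfectly adapted patch: fixed genotype at the optimum, no
# environmental noise, so viability selection is neutral (survival = 1)
perfect_patch_state <- function(sp, gp = genetic_params(), n0 = 100L,
                                seed = 1L) {
  w <- one_cell_world()
  init_state(w$ls, w$scn, sp, gp, presence = TRUE, single_genotype = TRUE,
             VE = c(0, 0, 0), n0_adults = n0, seed = seed)
}

# run a state for `years` years in burn-in mode, returning the per-year
# adult counts
run_adult_series <- function(state, years) {
  vapply(seq_len(years), function(i) {
    state <<- run_year(state, year = state$year, mode = "burn_in")
    sum(state$pop$stage == 3L)
  }, numeric(1))
}

# small multi-cell world with a linear warming scenario
make_test_world <- function(nr = 4, nc = 5, warm = 0.5) {
  temp <- matrix(seq(2, 8, length.out = nr * nc), nr, nc)
  precip <- matrix(seq(1000, 1800, length.out = nr * nc), nr, nc)
  carb <- matrix(rep(c(0, 100), length.out = nr * nc), nr, nc)
  ls <- landscape(temp, precip, carb)
  anchors <- seq(2010, 2090, 10)
  steps <- seq_along(anchors) - 1
  scn <- climate_scenario("test",
                          outer(ls$env[, 1], steps * warm, "+"),
                          outer(ls$env[, 2], steps * -5, "+"))
  list(ls = ls, scn = scn)
}

# internal container helpers, aliased for tests
subset_pop_for_test <- function(pop, idx) ecoevorange:::subset_pop(pop, idx)
pop_size_for_test <- function(pop) ecoevorange:::pop_size(pop)

stage_counts <- function(state) {
  c(seedling = sum(state$pop$stage == 1L),
    pre_adult = sum(state$pop$stage == 2L),
    adult = sum(state$pop$stage == 3L))
}
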
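# small evolving multi-cell state used by several engine tests
small_evolving_state <- function(seed = 17, single_genotype = FALSE) {
  spec <- fixture_spec(grid_shape = c(8L, 8L))
  ls <- make_landscape(spec, seed = 2)
  scn <- make_scenario(spec, "severe", ls)
  niche <- fixture_niche(spec)
  pp <- make_predictions(ls, niche, seed = 2)
  fits <- lapply(pp$predictions, binarize_suitability, truth = pp$truth)
  ens <- ensemble_suitability(pp$predictions,
                              vapply(fits, `[[`, numeric(1), "tss"))
  fit <- binarize_suitability(as.vector(ens), pp$truth)
  init_state(ls, scn, species_preset("synthetic"),
             genetic_params(mu = 0.001), fit$mask, niche = niche,
             single_genotype = single_genotype, n0_adults = 30L,
             seed = seed)
}

test_that("the yearly event log lists the life-cycle events in the canonical order", {
  st <- small_evolving_state()
  st <- run_year(st, mode = "scenario", year = 2001)
  expect_identical(st$event_log,
                   c("mating", "dispersal", "aging", "seedbank", "clonal",
                     "competition", "selection"))
  st <- run_year(st, year = st$year, mode = "burn_in")
  expect_identical(st$event_log,
                   c("mating", "dispersal", "aging", "seedbank", "clonal",
                     "competition", "selection", "ceiling_regulation"))
})

test_that("an empty landscape stays empty and one deterministic year matches a hand trace", {
  gp <- genetic_params(mu = 0)
  sp <- species_params(s_a = 1, fecundity = 0, germination = 1,
                       clonal_rate = 0, k_c = 0, seed_survival = 1,
                       max_seed_age = 3)
  st <- perfect_patch_state(sp, gp, n0 = 0L)
  for (i in 1:3) st <- run_year(st, year = st$year, mode = "burn_in")
  expect_identical(pop_size_for_test(st$pop), 0L)
  expect_identical(length(st$bank$cell), 0L)
  # hand trace with all transitions deterministic (rates 0 or 1):
  # 1 adult + 3 banked seeds, k_c = 0, perfect adaptation ->
  # after one year: the adult persists, all 3 seeds germinate, survive
  # competition (p = 1) and selection (z = theta), bank empties
  st2 <- perfect_patch_state(sp, gp, n0 = 1L)
  st2$bank <- list(cell = rep(1L, 3), age = integer(3), G = NULL)
  st2 <- run_year(st2, mode = "burn_in")
  expect_equal(unname(stage_counts(st2)), c(3, 0, 1))
  expect_identical(length(st2$bank$cell), 0L)
  # year 2: the three seedlings all become pre-adults
  st2 <- run_year(st2, mode = "burn_in")
  expect_equal(unname(stage_counts(st2)), c(0, 3, 1))
})

test_that("scenario runs record every tenth year from 2000 to 2150 and are seed-deterministic", {
  st <- small_evolving_state(single_genotype = TRUE)
  st <- burn_in(st, 30)
  set.seed(33)
  rec1 <- run_scenario(st, years = 2000:2150, record_interval = 10)
  expect_identical(sort(unique(rec1$year)), seq(2000L, 2150L, 10L))
  expect_identical(nrow(rec1), 16L * 64L)   # 16 record years x 64 cells
  expect_true(all(c("n_seed", "n_seedling", "n_pre_adult", "n_adult",
                    "g_mean_1", "g_var_3", "z_mean_2", "z_var_1",
                    "mean_fitness", "suitability", "occupied")
                  %in% names(rec1)))
  set.seed(33)
  rec2 <- run_scenario(st, years = 2000:2150, record_interval = 10)
  expect_identical(rec1, rec2)
})

test_that("burn-in honours zero ceilings and subsamples crowded patches", {
  st <- small_evolving_state()
  st <- burn_in(st, 25)
  outside <- which(!st$presence0)
  expect_false(any(st$pop$cell %in% outside))
  # all established pools bounded by the ceiling
  cnt <- tabulate(st$pop$cell, 64)
  expect_true(all(cnt <= st$ceiling))
})

test_that("single-genotype mode carries zero genetic variance and the grid-average genotype", {
  st <- small_evolving_state(single_genotype = TRUE)
  expect_null(st$pop$G)
  expect_equal(unname(apply(st$pop$gv, 2, stats::var)), c(0, 0, 0))
  st <- burn_in(st, 25)
  st <- run_year(st, year = 2000, mode = "scenario", record = TRUE)
  cen <- attr(st, "census")
  gv_cols <- as.matrix(cen[cen$occupied, c("g_var_1", "g_var_2", "g_var_3")])
  expect_true(all(abs(gv_cols) < 1e-10, na.rm = TRUE))
  gbar <- global_genotype(ecoevorange:::scale_env(st$ls, st$ls$env),
                          st$presence0)
  expect_true(all(abs(sweep(st$pop$gv, 2, gbar)) < 1e-12))
})

test_that("population snapshots round-trip bit-stably through their tabular form", {
  st <- small_evolving_state()
  st <- burn_in(st, 10)
  d1 <- file.path(tempdir(), "snap1")
  d2 <- file.path(tempdir(), "snap2")
  write_snapshot(st, d1)
  st2 <- read_snapshot(st, d1)
  write_snapshot(st2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  # and the restored state carries the same population
  expect_equal(st2$pop$cell, st$pop$cell)
  expect_equal(st2$pop$stage, st$pop$stage)
  expect_equal(genotypic_values(st2$pop$G, st$gp),
               genotypic_values(st$pop$G, st$gp), tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("occupancy change is the baseline-relative cell-count ratio", {
  # hand-built record table: 3 cells, occupancy 2 -> 2 -> 3 -> 0
  rec <- expand.grid(cell = 1:3, year = c(2000, 2010, 2020, 2030))
  rec$n_seedling <- 0
  rec$n_pre_adult <- 0
  rec$n_adult <- c(1, 1, 0,  2, 1, 0,  1, 1, 1,  0, 0, 0)
  oc <- occupancy_change(rec, baseline_year = 2010)
  expect_equal(oc$occupancy_change, c(0, 0, 0.5, -1))
  expect_error(occupancy_change(rec, baseline_year = 2005), "baseline")
  rec0 <- rec; rec0$n_adult <- 0
  expect_error(occupancy_change(rec0), "zero occupancy")
})

test_that("suitability classes equal brute-force set algebra on the occupancy masks", {
  rec <- expand.grid(cell = 1:4, year = c(2010, 2020))
  rec$n_seedling <- 0; rec$n_pre_adult <- 0
  #             cells:  1  2  3  4       1  2  3  4
  rec$n_adult <-     c(5, 3, 0, 0,      0, 2, 4, 0)
  rec$suitability <- c(800, 600, 400, 200, 700, 500, 300, 100)
  sc <- suitability_classes(rec, baseline_year = 2010)
  r2010 <- sc[sc$year == 2010, ]
  expect_equal(r2010$occupied, mean(c(800, 600)))
  expect_equal(r2010$unoccupied, mean(c(400, 200)))
  expect_true(is.na(r2010$colonized) && is.na(r2010$extinct))
  r2020 <- sc[sc$year == 2020, ]
  expect_equal(r2020$occupied, mean(c(500, 300)))
  expect_equal(r2020$unoccupied, mean(c(700, 100)))
  expect_equal(r2020$colonized, 300)   # cell 3 newly occupied
  expect_equal(r2020$extinct, 700)     # cell 1 lost
  # uniform suitability 0.5 reports 500 for every defined class
  rec$suitability <- 500
  sc2 <- suitability_classes(rec, baseline_year = 2010)
  expect_true(all(sc2$occupied == 500) && all(sc2$unoccupied == 500))
})

test_that("Haldane rates are definitional arithmetic", {
  expect_equal(haldane_rate(0, 0, 1.3, 10), 0)        # static climate
  expect_equal(haldane_rate(0, 1.5, 1.5, 10), 0.1)    # 1 sd over a decade
  expect_equal(haldane_rate(0, 1.5, 3.0, 10), 0.05)   # doubling sd halves
  expect_equal(haldane_rate(2, 1, 0.5, 10), -0.2)     # signed
  expect_error(haldane_rate(0, 1, 0, 10), "standard deviation")
  expect_error(haldane_rate(0, 1, 1, 0), "window")
})

test_that("configuration files round-trip and unknown keys are rejected", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "species:",
    "  preset: synthetic",
    "  fecundity: 12",
    "genetics:",
    "  mu: 0.01",
    "sim:",
    "  seed: 4",
    "  burn_in_years: 50"), cfg_path)
  cfg <- read_sim_config(cfg_path)
  expect_s3_class(cfg$species, "eer_species")
  expect_equal(cfg$species$fecundity, 12)
  expect_equal(cfg$genetics$mu, 0.01)
  expect_equal(cfg$sim$seed, 4)
  expect_equal(cfg$sim$burn_in_years, 50)
  expect_equal(cfg$sim$replicates, 3L)   # default filled in
  writeLines(c("species:", "  fecundty: 3"), cfg_path)
  expect_error(read_sim_config(cfg_path), "unknown key")
  writeLines(c("speciess:", "  fecundity: 3"), cfg_path)
  expect_error(read_sim_config(cfg_path), "unknown configuration section")
  unlink(cfg_path)
})
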
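# Year-loop scheduler: state initialisation, the fixed yearly event order,
# burn-in with ceiling regulation, climate-forcing scenario runs, and
# population snapshots.
#
# Yearly event order (census between competition and selection):
#   1 mating and seed production
#   2 seed dispersal
#   3 aging of adult and pre-adult individuals
#   4 seed germination and survival in the seedbank
#   5 clonal reproduction
#   6 seedling competition (density-dependent regulation)
#   7 seedling viability selection
# with an additional ceiling-regulation event, active during burn-in only,
# after selection.

LIFE_CYCLE_EVENTS <- c("mating", "dispersal", "aging", "seedbank",
                       "clonal", "competition", "selection")

#' Initialise a simulation state
#'
#' Builds the full simulator state for one grid: founder populations are
#' placed in every cell of the presence mask, each founder's genotypic
#' value is set exactly to the local environmental optimum (every allele
#' carries `optimum / 2L` per trait) and standing variation is added by
#' jittering every allelic effect by `N(0, v)`.  Populations start locally
#' adapted with large genetic and environmental variation.  The
#' environmental variance `VE` is calibrated once, from the realised
#' within-patch genetic variance of the founders, so that initial mean
#' heritability equals `gp$h2_target`; `VE` is then held fixed and
#' heritability is emergent thereafter.
#'
#' In single-genotype mode (`single_genotype = TRUE`) every individual
#' Trait values, optima and selection variances live on niche-width
#' units: each environmental variable is centred and scaled by its mean
#' and standard deviation over the predicted-occupied cells of the grid,
#' so the niche width `V_SENM` equals 1 per trait by construction and the
#' `vs_multiplier` acts directly as the selection variance.  This keeps
#' the fixed mutational variance `v`, the heritability-calibrated `VE`
#' and the selection variances on one commensurate scale, and makes the
#' multipliers comparable across variables.  Raw units are used for all
#' input/output.
#'
#' carries the fixed grid-average genotype of [global_genotype()];
#' mutation is disabled and the genotype cannot evolve, but individuals
#' disperse.  `VE` is then calibrated from the nominal initial genetic
#' variance `2 L v` per trait so both modes face comparable environmental
#' noise.
#'
#' @param ls An `eer_landscape`.
#' @param scenario An `eer_scenario` for the same grid.
#' @param sp An `eer_species` parameter set.
#' @param gp An `eer_genetics` parameter set.
#' @param presence Logical vector over cells: predicted-occupied mask from
#'   the niche-model post-processing.
#' @param vs_multiplier Selection-variance multiplier applied to the niche
#'   width `V_SENM` (1, 0.5 or 0.33 in the standard grid).
#' @param n0_adults Founder adults per occupied cell.
#' @param single_genotype Run the no-evolution, global-genotype baseline.
#' @param VE Optional per-trait environmental variance override.
#' @param niche Optional [niche_spec()] used by the suitability recorder.
#' @param seed Optional RNG seed set before founder genomes are drawn.
#' @return An `eer_state` list.
#' @export
init_state <- function(ls, scenario, sp, gp, presence, vs_multiplier = 1,
                       n0_adults = 50L, single_genotype = FALSE, VE = NULL,
                       niche = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  presence <- as.logical(presence)
  if (length(presence) != n_cells(ls))
    stop("presence mask must cover every cell")
  # traits and selection live on niche-width units: each environmental
  # variable is centred and scaled by its mean and sd over the
  # predicted-occupied cells, so V_SENM = 1 per trait by construction and
  # the fixed mutational variance v and the h2-calibrated VE are on a scale
  # commensurate with the selection variances
  occ_env <- ls$env[presence, , drop = FALSE]
  if (nrow(occ_env) >= 2L) {
    occ_sd <- apply(occ_env, 2, stats::sd)
    flat <- is.na(occ_sd) | occ_sd == 0
    if (any(flat)) {
      warning("zero niche width for: ",
              paste(colnames(ls$env)[flat], collapse = ", "),
              "; falling back to the landscape scale for these variables")
      occ_sd[flat] <- ls$scaling$sd[flat]
    }
    ls$scaling <- list(center = colMeans(occ_env), sd = occ_sd)
    envz <- scale_env(ls, ls$env)
    ns <- niche_summary(envz, presence)
    V_s <- selection_variance(ns$V_SENM, vs_multiplier)
  } else {
    # degenerate single-patch rigs: no niche width to anchor to, the
    # multiplier acts on the landscape scale directly
    ls$scaling <- list(center = occ_env[1, ], sd = ls$scaling$sd)
    envz <- scale_env(ls, ls$env)
    V_s <- rep(vs_multiplier, ncol(ls$env))
  }
  theta0 <- theta_at(ls, scenario, 2010, scaled = TRUE)
  cells <- rep(which(presence), each = n0_adults)
  n <- length(cells)
  Tt <- gp$n_traits

  if (single_genotype) {
    gbar <- global_genotype(envz, presence)
    fixed_genome <- as.vector(new_genomes(1L, gp, optimum = gbar))
    gp$mu <- 0
    gv <- matrix(rep(gbar, each = n), nrow = n, ncol = Tt)
    if (is.null(VE)) VE <- calibrate_VE(rep(2 * gp$L * gp$v, Tt),
                                        gp$h2_target)
    pop <- list(cell = cells, stage = rep(STAGE_ADULT, n),
                age = integer(n), G = NULL, gv = gv,
                z = express_phenotype(gv, VE))
    bank <- empty_bank(gp, with_genomes = FALSE)
  } else {
    fixed_genome <- NULL
    G <- seed_standing_variation(new_genomes(n, gp, theta0[cells, ,
                                                           drop = FALSE]),
                                 gp)
    gv <- genotypic_values(G, gp)
    if (is.null(VE)) {
      VG_within <- sapply(seq_len(Tt), function(t)
        mean(tapply(gv[, t], cells, stats::var), na.rm = TRUE))
      VE <- calibrate_VE(VG_within, gp$h2_target)
    }
    pop <- list(cell = cells, stage = rep(STAGE_ADULT, n),
                age = integer(n), G = G, gv = gv,
                z = express_phenotype(gv, VE))
    bank <- empty_bank(gp)
  }

  structure(list(
    ls = ls, scenario = scenario, sp = sp, gp = gp,
    V_s = V_s, VE = VE, niche = niche,
    presence0 = presence, theta0 = theta0,
    fixed_gv = if (single_genotype) global_genotype(envz, presence) else NULL,
    ceiling = ifelse(presence, sp$ceiling_K, 0),
    single_genotype = single_genotype, fixed_genome = fixed_genome,
    pop = pop, bank = bank, year = 2000L,
    event_log = character(0)
  ), class = "eer_state")
}

#' @export
print.eer_state <- function(x, ...) {
  st <- tabulate(x$pop$stage, 3L)
  cat(sprintf(
    "Simulation state (%s%s): year %d\n", x$sp$name,
    if (x$single_genotype) ", single-genotype baseline" else "", x$year))
  cat(sprintf("  %d seedlings, %d pre-adults, %d adults; %d banked seeds\n",
              st[1], st[2], st[3], bank_size(x$bank)))
  cat(sprintf("  occupied cells: %d of %d\n",
              length(unique(x$pop$cell)), n_cells(x$ls)))
  invisible(x)
}

# offspring genomes for mother/father index vectors; handles the
# single-genotype (no-evolution) mode
offspring_genomes <- function(state, mothers, fathers) {
  if (state$single_genotype) return(NULL)
  mutate_genomes(inherit_genomes(state$pop$G, state$pop$G, mothers,
                                 fathers, state$gp), state$gp)
}

# sample, for each seed, a father uniformly among the adults of the
# mother's cell (selfing permitted)
sample_fathers <- function(cells_of_seed, adult_idx, adult_cells, ncell) {
  tab <- tabulate(adult_cells, ncell)
  ord <- order(adult_cells)
  sorted_adults <- adult_idx[ord]
  offset <- c(0L, cumsum(tab))
  u <- floor(stats::runif(length(cells_of_seed)) * tab[cells_of_seed]) + 1L
  sorted_adults[offset[cells_of_seed] + u]
}

#' Advance the simulation by one year
#'
#' Executes the seven life-cycle events in the fixed order (see the event
#' list in [LIFE_CYCLE_EVENTS]), takes the census between competition and
#' selection, and (burn-in mode only) applies ceiling regulation after
#' selection.  In burn-in mode the optima are frozen at their initial
#' values; in scenario mode they follow the climate scenario at `year`.
#'
#' @param state An `eer_state`.
#' @param year Calendar year (defaults to `state$year + 1`).
#' @param mode `"scenario"` or `"burn_in"`.
#' @param record If `TRUE`, attach the per-cell census table as attribute
#'   `"census"` of the returned state.
#' @return The updated state; `state$event_log` lists the events executed.
#' @export
run_year <- function(state, year = state$year + 1L,
                     mode = c("scenario", "burn_in"), record = FALSE) {
  mode <- match.arg(mode)
  sp <- state$sp; gp <- state$gp; ls <- state$ls
  ncell <- n_cells(ls)
  theta <- if (mode == "burn_in") state$theta0 else
    theta_at(ls, state$scenario, year)
  pop <- state$pop
  log <- character(0)

  ## 1 -- mating and seed production
  adults <- which(pop$stage == STAGE_ADULT)
  if (length(adults) > 0L && sp$fecundity > 0) {
    brood <- stats::rpois(length(adults), sp$fecundity)
    mothers <- rep(adults, brood)
  } else {
    mothers <- integer(0)
  }
  if (length(mothers) > 0L) {
    seed_cells <- pop$cell[mothers]
    fathers <- sample_fathers(seed_cells, adults, pop$cell[adults], ncell)
    seed_G <- offspring_genomes(state, mothers, fathers)
  } else {
    seed_cells <- integer(0)
    seed_G <- if (state$single_genotype) NULL else new_genomes(0L, gp)
  }
  log <- c(log, "mating")

  ## 2 -- seed dispersal (new seeds only; off-grid seeds are lost)
  if (length(seed_cells) > 0L) {
    landed <- disperse_seeds(seed_cells, ls, sp$disperse_frac,
                             sp$disperse_mean)
    keep <- !is.na(landed)
    seed_cells <- landed[keep]
    if (!is.null(seed_G)) seed_G <- seed_G[keep, , drop = FALSE]
  }
  log <- c(log, "dispersal")

  ## 3 -- aging of adult and pre-adult individuals
  n <- pop_size(pop)
  if (n > 0L) {
    u <- stats::runif(n)
    die <- (pop$stage >= STAGE_PREADULT) & (u >= sp$s_a)
    pop <- subset_pop(pop, !die)
    promote <- pop$stage == STAGE_PREADULT & pop$age >= sp$maturation_years
    pop$stage[promote] <- STAGE_ADULT
    pop$age[promote] <- 0L
    still_pre <- pop$stage == STAGE_PREADULT
    pop$age[still_pre] <- pop$age[still_pre] + 1L
    was_seedling <- pop$stage == STAGE_SEEDLING
    pop$stage[was_seedling] <- STAGE_PREADULT
    pop$age[was_seedling] <- 1L
  }
  log <- c(log, "aging")

  ## 4 -- seed germination and seedbank survival
  bank <- bind_banks(state$bank,
                     list(cell = seed_cells,
                          age = integer(length(seed_cells)), G = seed_G))
  nb <- bank_size(bank)
  if (nb > 0L) {
    germ <- stats::runif(nb) < sp$germination
    sprout <- subset_bank(bank, germ)
    rest <- subset_bank(bank, !germ)
    surv <- stats::runif(bank_size(rest)) < sp$seed_survival
    rest <- subset_bank(rest, surv)
    rest$age <- rest$age + 1L
    bank <- subset_bank(rest, rest$age <= sp$max_seed_age)
    if (bank_size(sprout) > 0L) {
      if (state$single_genotype) {
        gv <- matrix(state$fixed_gv, nrow = bank_size(sprout),
                     ncol = gp$n_traits, byrow = TRUE)
        Gs <- NULL
      } else {
        Gs <- sprout$G
        gv <- genotypic_values(Gs, gp)
      }
      seedlings <- list(cell = sprout$cell,
                        stage = rep(STAGE_SEEDLING, bank_size(sprout)),
                        age = integer(bank_size(sprout)),
                        G = Gs, gv = gv,
                        z = express_phenotype(gv, state$VE))
      pop <- bind_pops(pop, seedlings)
    }
  }
  log <- c(log, "seedbank")

  ## 5 -- clonal reproduction (adults and pre-adults; clones pass through
  ##      the mutation step as any genome-copying event)
  if (sp$clonal_rate > 0) {
    par_idx <- which(pop$stage >= STAGE_PREADULT)
    if (length(par_idx) > 0L) {
      nkids <- stats::rpois(length(par_idx), sp$clonal_rate)
      parents <- rep(par_idx, nkids)
      if (length(parents) > 0L) {
        if (state$single_genotype) {
          Gc <- NULL
          gv <- pop$gv[parents, , drop = FALSE]
        } else {
          Gc <- mutate_genomes(pop$G[parents, , drop = FALSE], gp)
          gv <- genotypic_values(Gc, gp)
        }
        clones <- list(cell = pop$cell[parents],
                       stage = rep(STAGE_SEEDLING, length(parents)),
                       age = integer(length(parents)),
                       G = Gc, gv = gv,
                       z = express_phenotype(gv, state$VE))
        pop <- bind_pops(pop, clones)
      }
    }
  }
  log <- c(log, "clonal")

  ## 6 -- seedling competition against established plants
  est_stages <- if (sp$competition_pool == "adults") STAGE_ADULT else
    c(STAGE_PREADULT, STAGE_ADULT)
  n_est <- tabulate(pop$cell[pop$stage %in% est_stages], ncell)
  p_comp <- competition_survival(n_est, sp$k_c)
  sl <- pop$stage == STAGE_SEEDLING
  if (any(sl)) {
    die <- sl & (stats::runif(pop_size(pop)) >= p_comp[pop$cell])
    pop <- subset_pop(pop, !die)
  }
  log <- c(log, "competition")

  ## census: after competition, before selection
  sl_idx <- which(pop$stage == STAGE_SEEDLING)
  w_fit <- if (length(sl_idx) > 0L)
    viability_survival(pop$z[sl_idx, , drop = FALSE],
                       theta[pop$cell[sl_idx], , drop = FALSE],
                       state$V_s)
  else numeric(0)
  census <- if (record)
    census_table(pop, bank, sl_idx, w_fit, ncell, year, gp) else NULL

  ## 7 -- seedling viability selection
  if (length(sl_idx) > 0L) {
    die <- logical(pop_size(pop))
    die[sl_idx] <- stats::runif(length(sl_idx)) >= w_fit
    pop <- subset_pop(pop, !die)
  }
  log <- c(log, "selection")

  ## burn-in only: ceiling regulation of the established pool
  if (mode == "burn_in") {
    cnt <- tabulate(pop$cell, ncell)
    over <- which(cnt > state$ceiling)
    if (length(over) > 0L) {
      drop <- logical(pop_size(pop))
      for (cl in over) {
        here <- which(pop$cell == cl)
        keep <- ceiling_retain(length(here), state$ceiling[cl])
        drop[here[-keep]] <- TRUE
        if (length(keep) == 0L) drop[here] <- TRUE
      }
      pop <- subset_pop(pop, !drop)
    }
    if (any(cnt > 10 * max(state$ceiling)))
      stop("burn-in demographic explosion: patch exceeds 10x ceiling")
    log <- c(log, "ceiling_regulation")
  }

  state$pop <- pop
  state$bank <- bank
  state$year <- as.integer(year)
  state$event_log <- log
  if (record) attr(state, "census") <- census
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-cell census table at the census point
census_table <- function(pop, bank, sl_idx, w_fit, ncell, year, gp) {
  cnt <- function(idx) tabulate(pop$cell[idx], ncell)
  n_seedling <- cnt(pop$stage == STAGE_SEEDLING)
  n_pre <- cnt(pop$stage == STAGE_PREADULT)
  n_adult <- cnt(pop$stage == STAGE_ADULT)
  n_seed <- tabulate(bank$cell, ncell)
  out <- data.frame(year = year, cell = seq_len(ncell),
                    n_seed = n_seed, n_seedling = n_seedling,
                    n_pre_adult = n_pre, n_adult = n_adult)
  est <- pop$stage >= STAGE_SEEDLING   # all established individuals
  n_here <- tabulate(pop$cell[est], ncell)
  for (t in seq_len(gp$n_traits)) {
    gs <- rowsum_vec(pop$gv[est, t], pop$cell[est], ncell)
    gs2 <- rowsum_vec(pop$gv[est, t]^2, pop$cell[est], ncell)
    zs <- rowsum_vec(pop$z[est, t], pop$cell[est], ncell)
    zs2 <- rowsum_vec(pop$z[est, t]^2, pop$cell[est], ncell)
    gm <- ifelse(n_here > 0, gs / n_here, NA_real_)
    zm <- ifelse(n_here > 0, zs / n_here, NA_real_)
    out[[paste0("g_mean_", t)]] <- gm
    out[[paste0("g_var_", t)]] <-
      ifelse(n_here > 1, (gs2 - n_here * gm^2) / (n_here - 1), NA_real_)
    out[[paste0("z_mean_", t)]] <- zm
    out[[paste0("z_var_", t)]] <-
      ifelse(n_here > 1, (zs2 - n_here * zm^2) / (n_here - 1), NA_real_)
  }
  fit_sum <- rowsum_vec(w_fit, pop$cell[sl_idx], ncell)
  out$mean_fitness <- ifelse(n_seedling > 0, fit_sum / n_seedling, NA_real_)
  out$occupied <- (n_seedling + n_pre + n_adult) > 0
  out
}

rowsum_vec <- function(x, group, ncell) {
  out <- numeric(ncell)
  if (length(x) > 0L) {
    s <- rowsum(x, group)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Burn-in phase
#'
#' Runs the state for `years` years in burn-in mode: optima frozen at their
#' initial values and ceiling regulation active (capacity 0 outside the
#' predicted range, a large ceiling inside), letting populations reach
#' their mutation-selection-migration and demographic equilibria without
#' range expansion or demographic explosion.  Equilibrium diagnostics
#' (linear trend of total adults and mean genetic variance over the final
#' 10% of years) are attached.
#'
#' @param state An `eer_state`.
#' @param years Number of burn-in years.
#' @param progress_every If positive, message progress that often.
#' @return The equilibrated state with attribute `"diagnostics"`: a list
#'   with the adult and V_G series and the fitted end-phase trends.
#' @export
burn_in <- function(state, years, progress_every = 0) {
  adults <- numeric(years)
  vg <- numeric(years)
  for (i in seq_len(years)) {
    state <- run_year(state, year = state$year, mode = "burn_in")
    adults[i] <- sum(state$pop$stage == STAGE_ADULT)
    vg[i] <- if (pop_size(state$pop) > 1)
      mean(apply(state$pop$gv, 2, stats::var)) else 0
    if (adults[i] == 0 && i > 10 && all(adults[(i - 10):i] == 0))
      stop(sprintf(
        "global extinction during burn-in at year %d of %d (peak adults %d)",
        i, years, max(adults)))
    if (progress_every > 0 && i %% progress_every == 0)
      message(sprintf("burn-in year %d/%d: %d adults", i, years, adults[i]))
  }
  tail_n <- max(10L, ceiling(years * 0.1))
  idx <- seq.int(years - tail_n + 1L, years)
  fit_a <- stats::lm(adults[idx] ~ idx)
  fit_v <- stats::lm(vg[idx] ~ idx)
  attr(state, "diagnostics") <- list(
    adults = adults, VG = vg,
    adult_trend = stats::coef(fit_a)[2],
    adult_trend_ci = stats::confint(fit_a)[2, ],
    VG_trend = stats::coef(fit_v)[2])
  state
}

#' Climate-scenario phase
#'
#' Simulates `years` (default 2000-2150) in scenario mode: optima follow
#' the climate scenario, interpolated annually between the decadal anchors
#' (held at 2010 values before 2010 and constant after 2090), with no
#' ceiling regulation.  Census records are collected at `record_interval`-
#' year intervals.
#'
#' @param state An `eer_state`, typically the output of [burn_in()].
#' @param years Integer vector of calendar years to simulate.
#' @param record_interval Interval in years between census records.
#' @return A data frame of per-cell census records (one block per record
#'   year), with the per-cell suitability (probability of presence x 1000,
#'   from the state's niche description if present) in column
#'   `suitability`.
#' @export
run_scenario <- function(state, years = 2000:2150, record_interval = 10) {
  record_years <- years[(years - years[1]) %% record_interval == 0]
  recs <- vector("list", length(record_years))
  k <- 0L
  for (y in years) {
    rec <- y %in% record_years
    state <- run_year(state, year = y, mode = "scenario", record = rec)
    if (rec) {
      k <- k + 1L
      tab <- attr(state, "census")
      if (!is.null(state$niche))
        tab$suitability <- 1000 * project_suitability(
          state$ls, state$scenario, state$niche, y)
      recs[[k]] <- tab
    }
  }
  out <- do.call(rbind, recs[seq_len(k)])
  attr(out, "final_state") <- state
  out
}

#' Tabular population snapshots
#'
#' Serialises the established population and seedbank to plain-text tables
#' for burn-in save/restore: `individuals.csv` (id, cell, stage, age,
#' phenotypes), `alleles.csv` (one row per allele: individual id, locus,
#' copy, trait effects), `bank.csv` and `bank_alleles.csv`.
#' `read_snapshot()` restores them into a state; a save-load-save round
#' trip reproduces identical files.
#'
#' @param state An `eer_state`.
#' @param dir Directory to write to (created if needed).
#' @return `write_snapshot` returns `dir` invisibly; `read_snapshot`
#'   returns the state with population and bank replaced.
#' @export
write_snapshot <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- state$pop
  ind <- data.frame(individual = seq_len(pop_size(pop)), cell = pop$cell,
                    stage = pop$stage, age = pop$age)
  for (t in seq_len(state$gp$n_traits)) {
    ind[[paste0("gv_", t)]] <- pop$gv[, t]
    ind[[paste0("z_", t)]] <- pop$z[, t]
  }
  utils::write.csv(ind, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  bank <- state$bank
  utils::write.csv(data.frame(seed = seq_len(bank_size(bank)),
                              cell = bank$cell, age = bank$age),
                   file.path(dir, "bank.csv"), row.names = FALSE)
  if (!state$single_genotype) {
    utils::write.csv(genomes_to_alleles(pop$G, state$gp),
                     file.path(dir, "alleles.csv"), row.names = FALSE)
    ba <- genomes_to_alleles(bank$G, state$gp)
    names(ba)[1] <- "seed"
    utils::write.csv(ba, file.path(dir, "bank_alleles.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(state, dir) {
  gp <- state$gp
  ind <- utils::read.csv(file.path(dir, "individuals.csv"))
  n <- nrow(ind)
  Tt <- gp$n_traits
  gv <- as.matrix(ind[paste0("gv_", seq_len(Tt))])
  z <- as.matrix(ind[paste0("z_", seq_len(Tt))])
  dimnames(gv) <- dimnames(z) <- NULL
  G <- NULL
  if (!state$single_genotype) {
    al <- utils::read.csv(file.path(dir, "alleles.csv"))
    G <- alleles_to_genomes(al, gp)
    if (nrow(G) < n) G <- rbind(G, new_genomes(n - nrow(G), gp))
  }
  state$pop <- list(cell = as.integer(ind$cell),
                    stage = as.integer(ind$stage),
                    age = as.integer(ind$age), G = G, gv = gv, z = z)
  bk <- utils::read.csv(file.path(dir, "bank.csv"))
  Gb <- NULL
  if (!state$single_genotype) {
    bal <- utils::read.csv(file.path(dir, "bank_alleles.csv"))
    names(bal)[1] <- "individual"
    Gb <- alleles_to_genomes(bal, gp)
    if (nrow(Gb) < nrow(bk)) Gb <- rbind(Gb, new_genomes(nrow(bk) -
                                                           nrow(Gb), gp))
  }
  state$bank <- list(cell = as.integer(bk$cell), age = as.integer(bk$age),
                     G = Gb)
  state
}
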
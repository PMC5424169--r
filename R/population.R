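# Flat population containers.  Established individuals (seedlings,
# pre-adults, adults) live in a column-parallel list: integer vectors
# `cell`, `stage`, `age`, the genome matrix `G` (NULL in single-genotype
# runs), genotypic values `gv` and phenotypes `z` (n x T matrices).
# Stage codes: 1 = seedling, 2 = pre-adult, 3 = adult.

STAGE_SEEDLING <- 1L
STAGE_PREADULT <- 2L
STAGE_ADULT <- 3L

empty_population <- function(gp, with_genomes = TRUE) {
  list(cell = integer(0), stage = integer(0), age = integer(0),
       G = if (with_genomes) new_genomes(0L, gp) else NULL,
       gv = matrix(0, 0, gp$n_traits), z = matrix(0, 0, gp$n_traits))
}

pop_size <- function(pop) length(pop$cell)

subset_pop <- function(pop, idx) {
  list(cell = pop$cell[idx], stage = pop$stage[idx], age = pop$age[idx],
       G = if (is.null(pop$G)) NULL else pop$G[idx, , drop = FALSE],
       gv = pop$gv[idx, , drop = FALSE], z = pop$z[idx, , drop = FALSE])
}

bind_pops <- function(a, b) {
  list(cell = c(a$cell, b$cell), stage = c(a$stage, b$stage),
       age = c(a$age, b$age),
       G = if (is.null(a$G) || is.null(b$G)) NULL else rbind(a$G, b$G),
       gv = rbind(a$gv, b$gv), z = rbind(a$z, b$z))
}

empty_bank <- function(gp, with_genomes = TRUE) {
  list(cell = integer(0), age = integer(0),
       G = if (with_genomes) new_genomes(0L, gp) else NULL)
}

bank_size <- function(bank) length(bank$cell)

subset_bank <- function(bank, idx) {
  list(cell = bank$cell[idx], age = bank$age[idx],
       G = if (is.null(bank$G)) NULL else bank$G[idx, , drop = FALSE])
}

bind_banks <- function(a, b) {
  list(cell = c(a$cell, b$cell), age = c(a$age, b$age),
       G = if (is.null(a$G) || is.null(b$G)) NULL else rbind(a$G, b$G))
}
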
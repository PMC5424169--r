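# Diploid multilocus pleiotropic genetic architecture.
#
# A population's genomes are stored as a single numeric matrix with one row
# per individual and 2*L*T columns of real-valued allelic effects: L unlinked
# additive loci, 2 homologous copies per locus, T pleiotropic trait effects
# per allele.  Column layout for (locus l, copy c, trait t), all 1-based:
#   column = ((l - 1) * 2 + (c - 1)) * T + t
# so each allele occupies T consecutive columns and trait t is found in
# columns seq(t, 2*L*T, by = T).

#' Genetic architecture parameters
#'
#' Bundles the constants of the quantitative-genetic model: the number of
#' unlinked additive diploid loci `L`, the per-allele mutation rate `mu`
#' (per genome copying event), the per-trait mutational effect variance `v`
#' of the continuum-of-alleles model, the number of pleiotropic traits
#' `n_traits`, and the target narrow-sense heritability `h2_target` used to
#' calibrate the environmental variance at initialisation.
#'
#' @param L Integer, number of loci per trait set (default 10).
#' @param mu Per-allele mutation rate per generation, in \[0, 1\].
#' @param v Variance of each trait component of a mutational effect vector
#'   (default 0.05; effects are drawn i.i.d. Gaussian with no correlation
#'   across traits).
#' @param n_traits Number of pleiotropic traits per allele (default 3:
#'   temperature, precipitation, carbonate).
#' @param h2_target Heritability used by [calibrate_VE()] (default 0.3).
#' @return An object of class `eer_genetics`, a validated list.
#' @examples
#' gp <- genetic_params(mu = 0.001)
#' gp$v
#' @export
genetic_params <- function(L = 10L, mu = 0.001, v = 0.05, n_traits = 3L,
                           h2_target = 0.3) {
  L <- as.integer(L)
  n_traits <- as.integer(n_traits)
  if (L < 1L) stop("L must be a positive integer")
  if (!is.numeric(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (!is.numeric(v) || v < 0) stop("mutational variance v must be >= 0")
  if (n_traits < 1L) stop("n_traits must be >= 1")
  if (h2_target <= 0 || h2_target >= 1) stop("h2_target must lie in (0, 1)")
  structure(list(L = L, mu = mu, v = v, n_traits = n_traits,
                 h2_target = h2_target),
            class = "eer_genetics")
}

#' @export
print.eer_genetics <- function(x, ...) {
  cat(sprintf(
    "Genetic architecture: %d diploid loci x %d pleiotropic traits\n",
    x$L, x$n_traits))
  cat(sprintf("  mutation rate mu = %g per allele, effect variance v = %g\n",
              x$mu, x$v))
  cat(sprintf("  heritability target h2 = %g\n", x$h2_target))
  invisible(x)
}

n_genome_cols <- function(gp) 2L * gp$L * gp$n_traits

trait_cols <- function(gp, t) seq.int(t, n_genome_cols(gp), by = gp$n_traits)

#' Create a block of genomes
#'
#' Returns an `n` x `2*L*T` matrix of allelic effects.  With the default
#' `value = 0` all alleles are effect-free.  When `optimum` is supplied every
#' allele of every individual is set to `optimum / (2L)` per trait, so that
#' each genotypic value equals the local environmental optimum exactly.
#'
#' @param n Number of individuals.
#' @param gp A [genetic_params()] object.
#' @param optimum Optional length-`n_traits` vector, or `n` x `n_traits`
#'   matrix (one optimum per individual), of target genotypic values.
#' @return Numeric matrix of allelic effects.
#' @export
new_genomes <- function(n, gp, optimum = NULL) {
  G <- matrix(0, nrow = n, ncol = n_genome_cols(gp))
  if (!is.null(optimum) && n > 0L) {
    opt <- if (is.matrix(optimum)) optimum else
      matrix(optimum, nrow = n, ncol = gp$n_traits, byrow = TRUE)
    stopifnot(nrow(opt) == n, ncol(opt) == gp$n_traits)
    for (t in seq_len(gp$n_traits))
      G[, trait_cols(gp, t)] <- opt[, t] / (2 * gp$L)
  }
  G
}

#' Mutate genomes under the continuum-of-alleles model
#'
#' Each of the `2L` alleles of each genome mutates independently with
#' probability `gp$mu`.  A mutation draws a `n_traits`-dimensional Gaussian
#' effect vector with mean zero, variance `gp$v` per trait and no correlation
#' between traits, and adds it to the allele's existing effect values.
#'
#' @param G Genome matrix as produced by [new_genomes()].
#' @param gp A [genetic_params()] object.
#' @return The mutated genome matrix.
#' @export
mutate_genomes <- function(G, gp) {
  n <- nrow(G)
  if (n == 0L || gp$mu == 0) return(G)
  A <- 2L * gp$L
  hit <- which(stats::runif(n * A) < gp$mu)
  if (length(hit) == 0L) return(G)
  i <- ((hit - 1L) %% n) + 1L        # individual (column-major unfolding)
  a <- ((hit - 1L) %/% n) + 1L       # allele index in 1..2L
  Tt <- gp$n_traits
  idx <- cbind(rep(i, each = Tt),
               rep((a - 1L) * Tt, each = Tt) + seq_len(Tt))
  G[idx] <- G[idx] + stats::rnorm(nrow(idx), 0, sqrt(gp$v))
  G
}

#' Jitter every allele to create standing genetic variation
#'
#' Adds an independent `N(0, v)` deviate to every allelic effect value of
#' every genome, emulating a history of mutation accumulation before the
#' burn-in phase.  The expected genotypic variance contributed per trait is
#' `2 * L * v`.
#'
#' @inheritParams mutate_genomes
#' @return Jittered genome matrix.
#' @export
seed_standing_variation <- function(G, gp) {
  if (nrow(G) == 0L) return(G)
  G + matrix(stats::rnorm(length(G), 0, sqrt(gp$v)), nrow = nrow(G))
}

#' Mendelian inheritance with free recombination
#'
#' Builds offspring genomes: independently at each locus the offspring
#' receives one of the two homologous alleles of its mother (uniformly) and
#' one of the two of its father.  Loci are unlinked, so segregation is
#' independent across loci.
#'
#' @param Gm,Gf Genome matrices holding the maternal and paternal pools
#'   (may be the same matrix).
#' @param mothers,fathers Integer vectors of equal length indexing rows of
#'   `Gm` and `Gf`; element k gives the parents of offspring k.
#' @param gp A [genetic_params()] object.
#' @return Genome matrix with `length(mothers)` rows.
#' @export
inherit_genomes <- function(Gm, Gf, mothers, fathers, gp) {
  if (ncol(Gm) != ncol(Gf) || ncol(Gm) != n_genome_cols(gp))
    stop("parent genome matrices do not match the genetic architecture")
  n <- length(mothers)
  stopifnot(length(fathers) == n)
  Tt <- gp$n_traits
  G <- matrix(0, nrow = n, ncol = n_genome_cols(gp))
  if (n == 0L) return(G)
  rows <- seq_len(n)
  for (l in seq_len(gp$L)) {
    base <- (l - 1L) * 2L * Tt
    cm <- sample.int(2L, n, replace = TRUE)   # maternal copy transmitted
    cf <- sample.int(2L, n, replace = TRUE)   # paternal copy transmitted
    for (t in seq_len(Tt)) {
      G[cbind(rows, base + t)] <-
        Gm[cbind(mothers, base + (cm - 1L) * Tt + t)]
      G[cbind(rows, base + Tt + t)] <-
        Gf[cbind(fathers, base + (cf - 1L) * Tt + t)]
    }
  }
  G
}

#' Genotypic values
#'
#' The genotypic value of a trait is the sum of the effects of all `2L`
#' alleles contributing to that trait (purely additive architecture).
#'
#' @inheritParams mutate_genomes
#' @return An `nrow(G)` x `n_traits` matrix of genotypic values.
#' @export
genotypic_values <- function(G, gp) {
  out <- matrix(0, nrow = nrow(G), ncol = gp$n_traits)
  for (t in seq_len(gp$n_traits))
    out[, t] <- rowSums(G[, trait_cols(gp, t), drop = FALSE])
  out
}

#' Express phenotypes
#'
#' A phenotype is the genotypic value plus a random environmental deviation
#' drawn independently per trait and individual from a centred Gaussian with
#' variance `VE[k]`.
#'
#' @param gv Matrix of genotypic values (individuals x traits).
#' @param VE Length-`ncol(gv)` vector of environmental variances (>= 0).
#' @return Matrix of phenotypic values, same shape as `gv`.
#' @export
express_phenotype <- function(gv, VE) {
  if (any(VE < 0)) stop("environmental variances must be >= 0")
  if (length(VE) != ncol(gv)) stop("VE length must equal the trait count")
  n <- nrow(gv)
  if (n == 0L) return(gv)
  gv + matrix(stats::rnorm(n * ncol(gv), 0, rep(sqrt(VE), each = n)),
              nrow = n)
}

#' Calibrate environmental variance to a heritability target
#'
#' Returns the per-trait environmental variance `VE` such that
#' `VG / (VG + VE)` equals `h2_target` for each trait:
#' `VE = VG * (1 - h2) / h2`.
#'
#' @param VG Per-trait additive genetic variance (> 0).
#' @param h2_target Target narrow-sense heritability in (0, 1).
#' @return Per-trait environmental variance vector.
#' @export
calibrate_VE <- function(VG, h2_target) {
  if (h2_target <= 0 || h2_target >= 1) stop("h2_target must lie in (0, 1)")
  if (any(VG <= 0)) stop("VG must be > 0 to calibrate VE")
  VG * (1 - h2_target) / h2_target
}

#' Estimate narrow-sense heritability from a population sample
#'
#' Under the additive model, h2 per trait is the ratio of the sample
#' variance of genotypic values to the sample variance of phenotypic values.
#'
#' @param gv,z Matrices of genotypic and phenotypic values (individuals x
#'   traits), at least 2 rows.
#' @return Per-trait heritability vector.
#' @export
estimate_heritability <- function(gv, z) {
  if (nrow(gv) < 2L) stop("need at least 2 individuals")
  stopifnot(all(dim(gv) == dim(z)))
  VP <- apply(z, 2, stats::var)
  if (any(VP == 0)) stop("zero phenotypic variance: heritability undefined")
  apply(gv, 2, stats::var) / VP
}

#' Tabulate genomes as an allele table
#'
#' Serialises a genome matrix to a long-format data frame with one row per
#' allele (individual, locus, copy, then one column per trait effect), the
#' layout used by population snapshots.  [alleles_to_genomes()] inverts it.
#'
#' @inheritParams mutate_genomes
#' @return A data frame with columns `individual`, `locus`, `copy` and
#'   `effect_1` ... `effect_T`.
#' @export
genomes_to_alleles <- function(G, gp) {
  n <- nrow(G)
  Tt <- gp$n_traits
  A <- 2L * gp$L
  out <- data.frame(
    individual = rep(seq_len(n), times = A),
    locus = rep(rep(seq_len(gp$L), each = 2L), each = n),
    copy = rep(rep(1:2, times = gp$L), each = n)
  )
  for (t in seq_len(Tt)) {
    cols <- (rep(seq_len(A), each = n) - 1L) * Tt + t
    out[[paste0("effect_", t)]] <- G[cbind(rep(seq_len(n), times = A), cols)]
  }
  out
}

#' @rdname genomes_to_alleles
#' @param alleles Data frame produced by [genomes_to_alleles()].
#' @export
alleles_to_genomes <- function(alleles, gp) {
  n <- if (nrow(alleles)) max(alleles$individual) else 0L
  G <- matrix(0, nrow = n, ncol = n_genome_cols(gp))
  if (n == 0L) return(G)
  a <- (alleles$locus - 1L) * 2L + alleles$copy
  for (t in seq_len(gp$n_traits))
    G[cbind(alleles$individual, (a - 1L) * gp$n_traits + t)] <-
      alleles[[paste0("effect_", t)]]
  G
}
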
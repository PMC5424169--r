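# Density-dependent seedling competition, Gaussian viability selection and
# ceiling regulation.

#' Beverton-Holt seedling competition survival
#'
#' Probability that a seedling survives competition from the established
#' plants of its patch: `p = 1 / (1 + k_c * n_established)`.  `k_c` is the
#' competitive weight of an established (adult) individual; together with
#' the stage-transition rates it sets the carrying capacity at demographic
#' equilibrium.
#'
#' @param n_established Number of established competitors in the patch
#'   (vectorised).
#' @param k_c Competitive weight of an established individual (>= 0).
#' @return Survival probability (vectorised over `n_established`).
#' @export
competition_survival <- function(n_established, k_c) {
  if (any(n_established < 0)) stop("n_established must be >= 0")
  if (length(k_c) != 1L || k_c < 0) stop("k_c must be a scalar >= 0")
  1 / (1 + k_c * n_established)
}

#' Gaussian viability survival of seedlings
#'
#' Survival probability of an individual with phenotype vector `z` in a
#' patch whose optimum is `theta`:
#' `exp(-1/2 * sum_k (z_k - theta_k)^2 / V_s_k)`,
#' the multivariate Gaussian fitness surface with diagonal selection matrix
#' `W = diag(V_s)`.  Selection strength is inversely proportional to `V_s`.
#'
#' @param z Phenotype matrix (individuals x traits) or a single length-T
#'   vector.
#' @param theta Optimum: length-T vector or matrix conformable with `z`.
#' @param V_s Length-T vector of selection variances (> 0).
#' @return Vector of survival probabilities in (0, 1].
#' @export
viability_survival <- function(z, theta, V_s) {
  if (any(V_s <= 0)) stop("selection variances V_s must be > 0")
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (!is.matrix(theta))
    theta <- matrix(theta, nrow = nrow(z), ncol = ncol(z), byrow = TRUE)
  if (length(V_s) != ncol(z)) stop("V_s length must equal the trait count")
  d2 <- sweep((z - theta)^2, 2, V_s, "/")
  exp(-0.5 * rowSums(d2))
}

#' Ceiling regulation of a patch
#'
#' Burn-in-phase regulation event: patches with ceiling 0 are emptied;
#' where the number of established individuals exceeds the ceiling, a
#' uniform random subset of exactly the ceiling size is retained.  Applied
#' per patch to the established pool (seedlings, pre-adults, adults).
#'
#' @param keep_n Number of individuals currently in the patch.
#' @param K_ceiling Ceiling capacity (0 empties the patch).
#' @return Integer vector of indices (into `1:keep_n`) retained.
#' @export
ceiling_retain <- function(keep_n, K_ceiling) {
  if (K_ceiling <= 0) return(integer(0))
  if (keep_n <= K_ceiling) return(seq_len(keep_n))
  sort(sample.int(keep_n, K_ceiling))
}

#' Closed-form mean adaptive survival of an optimum-centred population
#'
#' For a population whose phenotypes are Gaussian around the local optimum
#' with per-trait variance `VP` (for a genetically uniform population at the
#' optimum, `VP = VE`), the expected Gaussian viability survival has the
#' closed form `prod_k sqrt(V_s_k / (V_s_k + VP_k))`.  Used as an
#' independent oracle for the adaptive-survival recorder.
#'
#' @param V_s Per-trait selection variances.
#' @param VP Per-trait phenotypic variances around the optimum.
#' @return Scalar expected survival.
#' @export
expected_adaptive_survival <- function(V_s, VP) {
  prod(sqrt(V_s / (V_s + VP)))
}
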
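# Static-niche-model post-processing: the pieces of correlative
# distribution modelling the simulator needs as inputs -- skill-weighted
# ensemble suitability, presence thresholding, niche-width extraction and
# the globally-averaged genotype used by the no-evolution baseline.
# Fitting the underlying statistical models is out of scope: per-model
# probability maps and truth labels are supplied (or fixture-generated).

#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(tn+fp) - 1`.
#' Ranges over \[-1, 1\]; 1 is a perfect classifier, 0 a skill-free one.
#'
#' @param tp,fp,tn,fn Nonnegative confusion-matrix counts.
#' @return Scalar TSS.
#' @export
tss <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if ((tp + fn) == 0 || (tn + fp) == 0)
    stop("TSS undefined: an observed class is empty")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

tss_of_mask <- function(pred, truth) {
  tss(tp = sum(pred & truth), fp = sum(pred & !truth),
      tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' TSS-weighted ensemble of suitability predictions
#'
#' Combines per-model occurrence-probability maps into one ensemble
#' forecast by weighted averaging, with weights proportional to each
#' model's TSS.  Models with TSS below `tss_min` (default 0.3) are
#' discarded.
#'
#' @param predictions List of numeric vectors/matrices of per-cell
#'   occurrence probabilities, one per model, identical shapes.
#' @param tss_scores Numeric vector of per-model TSS values.
#' @param tss_min Discard threshold (default 0.3).
#' @return Ensemble suitability of the same shape as the inputs, with the
#'   retained model indices and weights as attributes `retained` and
#'   `weights`.
#' @export
ensemble_suitability <- function(predictions, tss_scores, tss_min = 0.3) {
  if (length(predictions) != length(tss_scores))
    stop("one TSS score per prediction map required")
  keep <- which(tss_scores >= tss_min)
  if (length(keep) == 0L)
    stop("all models discarded: no TSS >= ", tss_min)
  w <- tss_scores[keep] / sum(tss_scores[keep])
  out <- predictions[[keep[1]]] * w[1]
  for (j in seq_along(keep)[-1])
    out <- out + predictions[[keep[j]]] * w[j]
  attr(out, "retained") <- keep
  attr(out, "weights") <- w
  out
}

#' Presence threshold maximising TSS
#'
#' Scans every distinct predicted probability as a candidate threshold,
#' declares presence where `probability >= threshold`, and returns the
#' threshold maximising the TSS against the truth labels (ties resolved to
#' the lowest threshold) together with the presence mask.
#'
#' @param prob Numeric vector of predicted occurrence probabilities.
#' @param truth Logical vector of observed presence.
#' @return List with `threshold`, `tss` and logical `mask`.
#' @export
binarize_suitability <- function(prob, truth) {
  if (length(prob) != length(truth)) stop("prob and truth lengths differ")
  truth <- as.logical(truth)
  if (all(truth) || !any(truth))
    stop("degenerate truth: both presence and absence records required")
  cand <- sort(unique(prob))
  if (length(cand) < 2L)
    stop("all predictions equal: threshold undefined")
  scores <- vapply(cand, function(th) tss_of_mask(prob >= th, truth),
                   numeric(1))
  best <- cand[which.max(scores)]   # which.max -> first (lowest) maximiser
  list(threshold = best, tss = max(scores), mask = prob >= best)
}

#' Niche summary over predicted-occupied cells
#'
#' Per-variable sample variance (`V_SENM`, the niche width used to anchor
#' the selection variances) and mean environment over the cells predicted
#' occupied.
#'
#' @param env ncell x T matrix of environmental values (use the landscape
#'   z-score scale when anchoring selection variances).
#' @param mask Logical presence mask over cells.
#' @return List with `V_SENM` and `mean_env` (length-T vectors) and
#'   `n_occupied`.
#' @export
niche_summary <- function(env, mask) {
  mask <- as.logical(mask)
  if (sum(mask) < 2L) stop("need at least 2 predicted-occupied cells")
  sub <- env[mask, , drop = FALSE]
  V <- apply(sub, 2, stats::var)
  if (any(V == 0))
    warning("zero niche width for: ",
            paste(colnames(sub)[V == 0], collapse = ", "),
            " (variable unusable for selection scaling)")
  list(V_SENM = V, mean_env = colMeans(sub), n_occupied = sum(mask))
}

#' Selection variances anchored to the niche width
#'
#' `V_s = multiplier * V_SENM` per trait; the niche width is taken as the
#' weakest plausible stabilising selection, with multipliers 1, 0.5 and
#' 0.33 giving progressively stronger selection.
#'
#' @param V_SENM Per-variable niche-width variances.
#' @param multiplier One of 1, 0.5, 0.33 for the standard grid (any
#'   positive value accepted).
#' @return Per-trait selection variance vector.
#' @export
selection_variance <- function(V_SENM, multiplier = 1) {
  if (multiplier <= 0) stop("multiplier must be > 0")
  if (any(V_SENM <= 0)) stop("V_SENM must be > 0 for all traits")
  multiplier * V_SENM
}

#' Grid-average genotype for the no-evolution baseline
#'
#' The single genotypic value used by the global-adaptation baseline: the
#' mean environmental value over the cells predicted occupied within the
#' grid (computed per grid to avoid a grid effect).  In single-genotype
#' runs every individual carries this fixed genotype, mutation is disabled
#' and the genotype does not evolve, but individuals still disperse.
#'
#' @inheritParams niche_summary
#' @return Length-T vector of genotypic values.
#' @export
global_genotype <- function(env, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("no predicted-occupied cells in grid")
  colMeans(env[mask, , drop = FALSE])
}

#' Niche description for fixture suitability surfaces
#'
#' A synthetic species niche: centre and width per environmental variable
#' (on the raw scale), with a logistic decay of suitability in scaled
#' distance from the centre.  Stands in for externally fitted
#' niche-model projections.
#'
#' @param center Length-T vector, niche centre in raw environmental units.
#' @param width Length-T vector of niche half-widths (scale of the distance
#'   metric), > 0.
#' @param edge Scaled distance at which suitability drops through 0.5
#'   (default 1).
#' @param steepness Logistic steepness (default 4).
#' @return An object of class `eer_niche`.
#' @export
niche_spec <- function(center, width, edge = 1, steepness = 4) {
  if (length(center) != length(width)) stop("center and width lengths differ")
  if (any(width <= 0)) stop("niche widths must be > 0")
  structure(list(center = center, width = width, edge = edge,
                 steepness = steepness), class = "eer_niche")
}

#' Project suitability from climate under a niche description
#'
#' Applies the logistic niche response to the (interpolated) environment of
#' a given year: suitability `= 1 / (1 + exp(steepness * (d - edge)))` with
#' `d` the Euclidean distance from the niche centre in width-scaled
#' environmental space.  A synthetic stand-in for time-projected
#' niche-model output, used by the suitability recorders.  Suitability
#' after 2090 equals the 2090 surface.
#'
#' @param ls An `eer_landscape`.
#' @param scenario An `eer_scenario`.
#' @param niche An [niche_spec()] object (raw environmental units).
#' @param year Calendar year.
#' @return Numeric vector of per-cell suitability in \[0, 1\].
#' @export
project_suitability <- function(ls, scenario, niche, year) {
  env <- theta_at(ls, scenario, min(year, 2090), scaled = FALSE)
  d <- sqrt(rowSums(sweep(sweep(env, 2, niche$center), 2,
                          niche$width, "/")^2))
  1 / (1 + exp(niche$steepness * (d - niche$edge)))
}
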
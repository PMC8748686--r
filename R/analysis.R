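# Cohort-level analytics: best-of-N model selection, cumulative success
# curves, pLDDT confidence statistics, motif calling, hotspot confusion.

#' Select the best model among the first n by a metric
#'
#' Mirrors the merged-protocol assessment rule: performance per complex is
#' that of the best model (lowest metric value) among the first `n` models
#' generated, e.g. the best RMSD model among 10 (five linked plus five
#' separate-chain models). Ties keep the lowest model index.
#'
#' @param models data.frame of per-model metrics (rows in generation order),
#'   e.g. from [evaluateComplex()].
#' @param key metric column to minimise (default `"rmsBB_if"`).
#' @param n how many leading models to consider (default all).
#' @return the selected row of `models` (one-row data.frame).
#' @export
bestOfN <- function(models, key = "rmsBB_if", n = nrow(models)) {
  if (!nrow(models)) stop("no models to select from")
  if (!key %in% names(models)) stop("unknown metric: ", key)
  head_ <- models[seq_len(min(n, nrow(models))), , drop = FALSE]
  vals <- head_[[key]]
  if (all(is.na(vals))) return(head_[1, , drop = FALSE])
  head_[which.min(vals), , drop = FALSE]
}

#' Cumulative success curve over a cohort of complexes
#'
#' For each RMSD threshold, the fraction of complexes whose best model lies
#' at or below it. Default thresholds include the conventional 1.5 (sub-
#' angstrom quality), 2.5 (accurate) and 5.0 (near-native) Angstrom marks.
#'
#' @param bestValues numeric vector, one best-model RMSD per complex.
#' @param thresholds Angstrom thresholds (default `c(1.5, 2.5, 5.0)`).
#' @return data.frame with columns `threshold` and `fraction`, plus
#'   attributes `n_complexes`.
#' @export
successCurve <- function(bestValues, thresholds = c(1.5, 2.5, 5.0)) {
  if (!length(bestValues)) stop("no complexes")
  fraction <- vapply(thresholds,
                     function(t) mean(bestValues <= t, na.rm = FALSE),
                     numeric(1))
  out <- data.frame(threshold = thresholds, fraction = fraction)
  attr(out, "n_complexes") <- length(bestValues)
  out
}

#' Confidence-accuracy confusion statistics for per-residue pLDDT
#'
#' Classifies each residue as predicted-accurate iff its pLDDT exceeds
#' `plddtCutoff` (strictly) and as actually accurate iff its RMSD is at most
#' `rmsdCutoff`, then tabulates the confusion counts. `precision` is the
#' fraction of high-confidence residues that are actually accurate;
#' `miss_rate` is the fraction of accurate residues with pLDDT at or below
#' the cutoff (accurate predictions missed by the confidence filter).
#'
#' @param perResidue data.frame (or list) with elements/columns `plddt` (in
#'   \[0,1\]) and `rmsd` (Angstrom).
#' @param plddtCutoff confidence cutoff (default 0.7).
#' @param rmsdCutoff accuracy cutoff in Angstrom (default 2.5).
#' @return list with `tp`, `fp`, `fn`, `tn`, `precision`, `miss_rate`,
#'   `plddt_cutoff`, `rmsd_cutoff`.
#' @export
plddtAccuracyStats <- function(perResidue, plddtCutoff = 0.7,
                               rmsdCutoff = 2.5) {
  plddt <- perResidue$plddt; rmsd <- perResidue$rmsd
  if (!length(plddt)) stop("no residues")
  if (length(plddt) != length(rmsd))
    stop("plddt and rmsd lengths differ")
  if (any(plddt < 0 | plddt > 1)) stop("plddt outside [0,1]")
  conf <- plddt > plddtCutoff
  acc <- rmsd <= rmsdCutoff
  tp <- sum(conf & acc); fp <- sum(conf & !acc)
  fn <- sum(!conf & acc); tn <- sum(!conf & !acc)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       miss_rate = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
       plddt_cutoff = plddtCutoff, rmsd_cutoff = rmsdCutoff)
}

#' Call candidate motifs from high-confidence residue runs
#'
#' Well-modeled binding motifs show up as runs of consecutive peptide
#' residues with high pLDDT. Returns maximal runs of residues with pLDDT
#' strictly above `cutoff` that are at least `minRun` residues long.
#'
#' @param plddt per-residue confidence values in \[0,1\].
#' @param cutoff confidence cutoff (default 0.7).
#' @param minRun minimum run length (default 3).
#' @return data.frame with half-open 0-based intervals `start`, `end`.
#' @export
callMotifs <- function(plddt, cutoff = 0.7, minRun = 3L) {
  if (!length(plddt)) stop("no residues")
  r <- rle(plddt > cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= minRun
  data.frame(start = starts[keep], end = ends[keep])
}

#' Hotspot confusion analysis of alanine-scanning ddG tables
#'
#' Compares per-residue alanine-scanning ddG values computed on a model with
#' those computed on the native structure. A residue is a hotspot iff its
#' ddG is at least `threshold` (default 1.5 kcal/mol). Counts the four
#' quadrants of the model-vs-native scatter (TP: hotspot in both; FP: model
#' only; FN: native only; TN: neither) and reports the Spearman rank
#' correlation of the paired ddG values (average ranks on ties).
#'
#' @param modelEntries,nativeEntries data.frames with columns `residue` and
#'   `ddG` (kcal/mol); the residue sets must pair exactly.
#' @param threshold hotspot threshold in kcal/mol (default 1.5).
#' @return list with `tp`, `fp`, `fn`, `tn`, `spearman_rho`, `threshold`.
#' @export
hotspotConfusion <- function(modelEntries, nativeEntries, threshold = 1.5) {
  unpaired <- c(setdiff(modelEntries$residue, nativeEntries$residue),
                setdiff(nativeEntries$residue, modelEntries$residue))
  if (length(unpaired))
    stop("unpaired residues: ", paste(unique(unpaired), collapse = ", "))
  ord <- match(modelEntries$residue, nativeEntries$residue)
  mod <- modelEntries$ddG
  nat <- nativeEntries$ddG[ord]
  if (any(!is.finite(c(mod, nat)))) stop("non-finite ddG values")
  hm <- mod >= threshold; hn <- nat >= threshold
  list(tp = sum(hm & hn), fp = sum(hm & !hn), fn = sum(!hm & hn),
       tn = sum(!hm & !hn),
       spearman_rho = stats::cor(mod, nat, method = "spearman"),
       threshold = threshold)
}

#' Mean peptide pLDDT of a predicted model
#'
#' Average confidence over the peptide residues only (linker and receptor
#' excluded); mean peptide pLDDT above 0.7 is the model-selection signal
#' associated with medium-to-high quality (DockQ > 0.6) models.
#'
#' @param model a [PredictedModel-class].
#' @return arithmetic mean confidence.
#' @export
meanPeptidePlddt <- function(model) {
  stopifnot(is(model, "PredictedModel"))
  q <- model@query
  n <- length(model@plddt)
  P <- nchar(q@peptideSeq)
  mean(model@plddt[seq.int(n - P + 1L, n)])
}
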
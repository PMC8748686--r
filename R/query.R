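# Predictor input construction: fused poly-Gly linker queries, separate-chain
# queries, poly-Ala controls, and run-configuration grids.

validateSeq <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " sequence must be a non-empty string")
  bad <- setdiff(strsplit(seq, "")[[1]], unname(STANDARD_AA3))
  if (length(bad))
    stop(what, " sequence contains non-standard letters: ",
         paste(unique(bad), collapse = ""))
  invisible(seq)
}

#' Run configuration for one prediction
#'
#' The protocol settings varied in the calibration grid: linkage mode, number
#' of recycles (3 or 9), use of environmental sequences, dropout, random
#' seed, and which of the five trained parameter sets is used.
#'
#' @param linkage `"linked"` or `"separate"`.
#' @param recycles positive integer recycle count.
#' @param useEnvSeqs,dropout logical flags.
#' @param seed integer random seed.
#' @param paramSet integer in 1..5.
#' @return named list of class `"RunConfig"`.
#' @export
runConfig <- function(linkage = "linked", recycles = 9L, useEnvSeqs = TRUE,
                      dropout = FALSE, seed = 1L, paramSet = 1L) {
  linkage <- match.arg(linkage, c("linked", "separate"))
  recycles <- as.integer(recycles)
  paramSet <- as.integer(paramSet)
  if (recycles < 1L) stop("recycles must be >= 1")
  if (!paramSet %in% 1:5) stop("paramSet must be in 1..5")
  structure(list(linkage = linkage, recycles = recycles,
                 useEnvSeqs = isTRUE(useEnvSeqs), dropout = isTRUE(dropout),
                 seed = as.integer(seed), paramSet = paramSet),
            class = "RunConfig")
}

#' Build a fused poly-glycine linker query
#'
#' Concatenates receptor and peptide with a glycine linker into one chain, in
#' the order (N-terminus) receptor - linker - peptide (C-terminus), so a
#' monomer structure predictor models the complex as a single chain whose
#' linker it recognises as unstructured.
#'
#' @param receptorSeq,peptideSeq one-letter sequences over the 20 standard
#'   amino acids.
#' @param linkerLength number of linker glycines (default 30).
#' @param config optional [runConfig()].
#' @return a [DockingQuery-class] with `linkage = "linked"`.
#' @examples
#' q <- buildLinkedQuery("MKVLA", "PPGY")
#' nchar(q@fusedSeq)  # 39
#' @export
buildLinkedQuery <- function(receptorSeq, peptideSeq, linkerLength = 30L,
                             config = runConfig(linkage = "linked")) {
  validateSeq(receptorSeq, "receptor"); validateSeq(peptideSeq, "peptide")
  linkerLength <- as.integer(linkerLength)
  if (linkerLength < 0L) stop("linkerLength must be >= 0")
  new("DockingQuery", receptorSeq = receptorSeq, peptideSeq = peptideSeq,
      linkage = "linked", linkerLength = linkerLength,
      fusedSeq = paste0(receptorSeq, strrep("G", linkerLength), peptideSeq),
      config = unclass(config))
}

#' Build a separate-chain query
#'
#' Receptor and peptide presented as two records, receptor first.
#'
#' @inheritParams buildLinkedQuery
#' @return a [DockingQuery-class] with `linkage = "separate"`.
#' @export
buildSeparateQuery <- function(receptorSeq, peptideSeq,
                               config = runConfig(linkage = "separate")) {
  validateSeq(receptorSeq, "receptor"); validateSeq(peptideSeq, "peptide")
  new("DockingQuery", receptorSeq = receptorSeq, peptideSeq = peptideSeq,
      linkage = "separate", linkerLength = 0L, fusedSeq = NA_character_,
      config = unclass(config))
}

#' Poly-alanine control variant of a query
#'
#' Mutates every peptide residue to alanine in the query sequence, keeping
#' the original peptide length, the receptor, and the linkage mode. Used to
#' probe whether the predictor relies on the peptide sequence or merely on
#' backbone complementarity.
#'
#' @param query a [DockingQuery-class].
#' @return the poly-Ala [DockingQuery-class].
#' @export
buildPolyAlaVariant <- function(query) {
  stopifnot(is(query, "DockingQuery"))
  ala <- strrep("A", nchar(query@peptideSeq))
  if (query@linkage == "linked")
    buildLinkedQuery(query@receptorSeq, ala, query@linkerLength,
                     config = structure(query@config, class = "RunConfig"))
  else
    buildSeparateQuery(query@receptorSeq, ala,
                       config = structure(query@config, class = "RunConfig"))
}

#' FASTA records of a query
#'
#' One record for a linked query (the fused chain), two records (receptor
#' then peptide) for a separate-chain query.
#'
#' @param query a [DockingQuery-class].
#' @return named character vector of sequences.
#' @export
queryRecords <- function(query) {
  stopifnot(is(query, "DockingQuery"))
  if (query@linkage == "linked")
    c(fused = query@fusedSeq)
  else
    c(receptor = query@receptorSeq, peptide = query@peptideSeq)
}

GRID_FACTORS <- c("linkage", "recycles", "useEnvSeqs", "dropout", "seed",
                  "paramSet")

#' Enumerate a run-configuration grid
#'
#' Cartesian product of factor levels in deterministic lexicographic order
#' (by linkage, recycles, useEnvSeqs, dropout, seed, paramSet; earlier
#' factors vary slowest). The calibration grid of 2 linkages x 2 recycle
#' settings x 2 environmental-sequence settings x 2 dropout settings x
#' 5 seeds x 5 parameter sets yields 2*2*2*2*5*5 = 400 configurations; the
#' merged default protocol (5 parameter sets x 2 linkages) yields the 10
#' models used for best-of-10 selection.
#'
#' @param factors named list mapping factor names (a subset of the six above)
#'   to non-empty value vectors; omitted factors take the [runConfig()]
#'   default.
#' @return list of `RunConfig` objects.
#' @examples
#' length(enumerateGrid(defaultCalibrationFactors()))  # 400
#' @export
enumerateGrid <- function(factors) {
  unknown <- setdiff(names(factors), GRID_FACTORS)
  if (length(unknown))
    stop("unknown factor name(s): ", paste(unknown, collapse = ", "))
  if (any(!lengths(factors)))
    stop("every factor must have at least one value")
  defaults <- unclass(runConfig())
  levels <- lapply(GRID_FACTORS, function(f)
    if (f %in% names(factors)) factors[[f]] else defaults[[f]])
  names(levels) <- GRID_FACTORS
  # expand.grid varies the first factor fastest; reverse for lexicographic
  grid <- expand.grid(rev(levels), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, GRID_FACTORS, drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    runConfig(linkage = grid$linkage[i], recycles = grid$recycles[i],
              useEnvSeqs = grid$useEnvSeqs[i], dropout = grid$dropout[i],
              seed = grid$seed[i], paramSet = grid$paramSet[i]))
}

#' @describeIn enumerateGrid the full 400-configuration calibration grid.
#' @export
defaultCalibrationFactors <- function() {
  list(linkage = c("linked", "separate"), recycles = c(3L, 9L),
       useEnvSeqs = c(TRUE, FALSE), dropout = c(FALSE, TRUE),
       seed = 1:5, paramSet = 1:5)
}

#' @describeIn enumerateGrid the merged default protocol: five parameter sets
#'   for each linkage mode, ten configurations in total.
#' @export
defaultProtocolFactors <- function() {
  list(linkage = c("linked", "separate"), recycles = 9L,
       useEnvSeqs = TRUE, dropout = FALSE, seed = 1L, paramSet = 1:5)
}

#' Write a run manifest for a batch of configurations
#'
#' @param configs list of `RunConfig` objects.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(configs, path) {
  yaml::write_yaml(lapply(configs, unclass), path)
  invisible(path)
}

#' @describeIn writeRunManifest read a manifest back.
#' @export
readRunManifest <- function(path) {
  lapply(yaml::read_yaml(path), function(cfg) do.call(runConfig, cfg))
}
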
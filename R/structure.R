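#' Construct a backbone structure object
#'
#' A minimal per-frame representation holding the backbone heavy atoms
#' (N, CA, C, O) for each residue, an optional amide hydrogen and an
#' optional side-chain centroid. Coordinates are in Angstrom. Residue
#' indexing is 1-based and preserved from the input file.
#'
#' @param residue_index integer vector, strictly increasing within a chain.
#' @param residue_name character vector of 3-letter residue codes.
#' @param n,ca,c,o numeric matrices (n_res x 3) of backbone coordinates.
#'   Terminal residues may carry NA rows only for atoms that genuinely do
#'   not exist (e.g. OXT handling is not modelled; O is required).
#' @param h optional (n_res x 3) matrix of amide hydrogen coordinates;
#'   rows of NA mean "not present, infer if needed".
#' @param sc optional (n_res x 3) matrix of side-chain centroids; NA rows
#'   for glycine or missing side chains.
#' @param chain chain identifier (single string).
#' @return object of class `hx_structure`.
#' @export
hx_structure <- function(residue_index, residue_name, n, ca, c, o,
                         h = NULL, sc = NULL, chain = "A") {
  nres <- length(residue_index)
  residue_index <- as.integer(residue_index)
  if (any(diff(residue_index) <= 0))
    stop("residue_index must be strictly increasing within a chain")
  if (length(residue_name) == 1L) residue_name <- rep(residue_name, nres)
  as_m <- function(x, what) {
    x <- as.matrix(x)
    if (nrow(x) != nres || ncol(x) != 3L)
      stop("coordinate matrix for ", what, " must be ", nres, " x 3")
    storage.mode(x) <- "double"
    x
  }
  n <- as_m(n, "N"); ca <- as_m(ca, "CA"); c <- as_m(c, "C"); o <- as_m(o, "O")
  core <- rbind(n, ca, c, o)
  if (any(!is.finite(core)))
    stop("backbone coordinates contain non-finite values")
  if (!is.null(h)) h <- as_m(h, "H")
  if (!is.null(sc)) sc <- as_m(sc, "SC")
  structure(list(residue_index = residue_index,
                 residue_name = toupper(residue_name),
                 chain = chain,
                 n = n, ca = ca, c = c, o = o, h = h, sc = sc),
            class = "hx_structure")
}

#' @export
print.hx_structure <- function(x, ...) {
  cat("hx_structure:", length(x$residue_index), "residues, chain",
      x$chain, "\n")
  cat("  residue_index:", x$residue_index[1], "..",
      x$residue_index[length(x$residue_index)], "\n")
  cat("  side-chain centroids:", if (is.null(x$sc)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure an `hx_structure`.
#' @return integer.
#' @export
n_residues <- function(structure) length(structure$residue_index)

#' Exchange-competent HDX sites of a structure
#'
#' The amide NH sites that can exchange: every residue except the first
#' in the chain (no preceding carbonyl, and the N-terminal amine is not
#' an amide) and except prolines (no amide hydrogen).
#'
#' @param structure an `hx_structure`.
#' @return integer vector of positions (1-based into the residue list).
#' @export
hdx_sites <- function(structure) {
  idx <- seq_along(structure$residue_index)
  keep <- idx > 1L & structure$residue_name != "PRO"
  idx[keep]
}

#' Construct a conformational ensemble
#'
#' @param frames list of `hx_structure` objects sharing one topology.
#' @param weights nonnegative per-frame weights (default all 1).
#' @param replica optional per-frame replica or temperature label.
#' @param energies optional (n_frames x n_states) matrix of potential
#'   energies in kcal mol^-1, for multistate reweighting.
#' @return object of class `hx_ensemble`.
#' @export
hx_ensemble <- function(frames, weights = NULL, replica = NULL,
                        energies = NULL) {
  if (length(frames) < 1L) stop("ensemble must contain at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "hx_structure")))
    stop("all frames must be hx_structure objects")
  ref <- frames[[1]]$residue_index
  same <- vapply(frames, function(f) identical(f$residue_index, ref),
                 logical(1))
  if (!all(same)) stop("all frames must share an identical residue topology")
  nf <- length(frames)
  if (is.null(weights)) weights <- rep(1, nf)
  if (length(weights) != nf || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative, one per frame, with positive sum")
  if (!is.null(energies)) {
    energies <- as.matrix(energies)
    if (nrow(energies) != nf) stop("energies must have one row per frame")
  }
  structure(list(frames = frames, weights = as.numeric(weights),
                 replica = replica, energies = energies),
            class = "hx_ensemble")
}

#' @export
print.hx_ensemble <- function(x, ...) {
  cat("hx_ensemble:", length(x$frames), "frames,",
      length(x$frames[[1]]$residue_index), "residues\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `hx_ensemble`.
#' @return integer.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)
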
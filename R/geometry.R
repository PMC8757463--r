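# Per-frame structural features: amide-H placement, H-bond scores,
# burial levels, radius of gyration, contact matrices.

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Infer the amide hydrogen position of a residue
#'
#' Coarse backbone representations carry no explicit amide hydrogens, so
#' the H is placed geometrically: 1.01 Angstrom from N, in the
#' C(prev)-N-CA plane, along the direction opposing the bisector of the
#' C(prev)->N and CA->N bonds. This reproduces the planar sp2 amide
#' geometry of a trans peptide bond.
#'
#' @param structure an `hx_structure`.
#' @param residue position (1-based into the residue list) of the amide.
#' @return length-3 numeric vector (Angstrom). Attribute `degenerate` is
#'   TRUE when the C(prev), N, CA atoms are collinear and a fallback
#'   direction perpendicular to the chain axis was used.
#' @export
infer_amide_hydrogen <- function(structure, residue) {
  i <- residue
  if (i <= 1L)
    stop("first residue of a chain has no preceding carbonyl; no amide H")
  if (structure$residue_name[i] == "PRO")
    stop("proline has no amide hydrogen")
  n  <- structure$n[i, ]
  ca <- structure$ca[i, ]
  cp <- structure$c[i - 1L, ]
  if (any(!is.finite(c(n, ca, cp))))
    stop("missing backbone atoms for amide-H inference at residue ", i)
  u1 <- vunit(cp - n)
  u2 <- vunit(ca - n)
  b <- u1 + u2
  degenerate <- FALSE
  if (vnorm(b) < 1e-6) {
    # collinear C(prev), N, CA: any direction perpendicular to the chain
    # axis is geometrically admissible; pick one deterministically
    degenerate <- TRUE
    axis <- u2
    trial <- c(1, 0, 0)
    if (abs(sum(trial * axis)) > 0.9) trial <- c(0, 1, 0)
    b <- -vunit(trial - sum(trial * axis) * axis)
  }
  h <- n + 1.01 * vunit(-b)
  attr(h, "degenerate") <- degenerate
  h
}

#' Backbone hydrogen-bond score
#'
#' A smooth, bimodal score in (0, 1) for an N-H...O=C hydrogen bond:
#' the product of a logistic distance switch on the H...O separation,
#' midpoint 2.5 Angstrom and width 0.25 Angstrom, and a logistic angular
#' switch on the N-H...O angle, midpoint 120 degrees and width 10
#' degrees. Formed bonds score near 1, broken ones near 0, and the score
#' is monotone (decreasing in distance, increasing in angle).
#'
#' @param donor_h,acceptor_o,donor_n,acceptor_c length-3 coordinates
#'   (Angstrom) of the amide H, carbonyl O, amide N and carbonyl C.
#' @return numeric score in (0, 1).
#' @export
hbond_score <- function(donor_h, acceptor_o, donor_n, acceptor_c) {
  d_ho <- vnorm(acceptor_o - donor_h)
  v1 <- donor_n - donor_h
  v2 <- acceptor_o - donor_h
  ct <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  ct <- min(1, max(-1, ct))
  theta <- acos(ct) * 180 / pi
  sig_d <- 1 / (1 + exp((d_ho - 2.5) / 0.25))
  sig_a <- 1 / (1 + exp((120 - theta) / 10))
  sig_d * sig_a
}

# All donor -> acceptor H-bond scores for one frame.
# Donors: hdx sites with an amide H (explicit or inferred); acceptors:
# backbone carbonyl O of residues with |i - j| >= min_sep.
# Returns a (n_donor x n_res) matrix with NA for excluded pairs.
hbond_score_matrix <- function(structure, min_sep = 2L) {
  nres <- n_residues(structure)
  sites <- hdx_sites(structure)
  out <- matrix(NA_real_, length(sites), nres,
                dimnames = list(site = NULL, acceptor = NULL))
  for (k in seq_along(sites)) {
    i <- sites[k]
    h <- if (!is.null(structure$h) && all(is.finite(structure$h[i, ])))
      structure$h[i, ] else infer_amide_hydrogen(structure, i)
    nn <- structure$n[i, ]
    for (j in seq_len(nres)) {
      if (abs(i - j) < min_sep) next
      o <- structure$o[j, ]
      cc <- structure$c[j, ]
      if (any(!is.finite(c(o, cc)))) next
      out[k, j] <- hbond_score(h, o, nn, cc)
    }
  }
  attr(out, "sites") <- sites
  out
}

#' Burial level of an amide hydrogen
#'
#' A smooth count of heavy atoms surrounding the amide H, the proxy used
#' to decide whether a broken NH is still shielded from solvent. Two
#' contributions are summed with logistic switches of midpoint `cutoff`
#' (default 6.5 Angstrom) and width 0.5 Angstrom: backbone heavy atoms
#' (N, CA, C, O) and side-chain centroids, both excluding the site's own
#' residue and its sequence neighbours (i-1, i+1). Because a centroid is
#' a single interaction centre standing for a whole side chain, the
#' total is `bl_bb + 5 * bl_sc`.
#'
#' @param structure an `hx_structure`.
#' @param site residue position of the amide NH.
#' @param cutoff switch midpoint in Angstrom (default 6.5).
#' @return list with `bl_bb`, `bl_sc`, `bl_total`.
#' @export
burial_level <- function(structure, site, cutoff = 6.5) {
  i <- site
  h <- if (!is.null(structure$h) && all(is.finite(structure$h[i, ])))
    structure$h[i, ] else infer_amide_hydrogen(structure, i)
  nres <- n_residues(structure)
  others <- setdiff(seq_len(nres), c(i - 1L, i, i + 1L))
  sw <- function(d) 1 / (1 + exp((d - cutoff) / 0.5))
  bl_bb <- 0
  if (length(others)) {
    pts <- rbind(structure$n[others, , drop = FALSE],
                 structure$ca[others, , drop = FALSE],
                 structure$c[others, , drop = FALSE],
                 structure$o[others, , drop = FALSE])
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts)) {
      d <- sqrt(rowSums(sweep(pts, 2, h)^2))
      bl_bb <- sum(sw(d))
    }
  }
  bl_sc <- 0
  if (!is.null(structure$sc) && length(others)) {
    pts <- structure$sc[others, , drop = FALSE]
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts)) {
      d <- sqrt(rowSums(sweep(pts, 2, h)^2))
      bl_sc <- sum(sw(d))
    }
  }
  list(bl_bb = bl_bb, bl_sc = bl_sc, bl_total = bl_bb + 5 * bl_sc)
}

#' Count backbone hydrogen bonds in a frame
#'
#' A donor NH is counted as H-bonded when its best acceptor score is at
#' or above the `hbond_made` threshold; each donor counts at most once,
#' so the result is the number of H-bonded amides.
#'
#' @param score_matrix donor x acceptor score matrix as produced
#'   internally from [hbond_score()] (NA entries are skipped), or an
#'   `hx_structure` from which it is computed.
#' @param hbond_made threshold on the bimodal score (default 0.5); the
#'   boundary is closed (a score exactly at threshold counts).
#' @return integer number of H-bonded donors.
#' @export
count_hbonds <- function(score_matrix, hbond_made = 0.5) {
  if (inherits(score_matrix, "hx_structure"))
    score_matrix <- hbond_score_matrix(score_matrix)
  if (!nrow(score_matrix)) return(0L)
  best <- apply(score_matrix, 1, function(r)
    if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  sum(best >= hbond_made)
}

#' Radius of gyration
#'
#' Mass-unweighted RMS distance of the C-alpha atoms from their
#' centroid, in Angstrom.
#'
#' @param structure an `hx_structure`.
#' @return numeric (Angstrom).
#' @export
radius_of_gyration <- function(structure) {
  ca <- structure$ca
  ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  if (!nrow(ca)) stop("no C-alpha coordinates")
  ctr <- colMeans(ca)
  sqrt(mean(rowSums(sweep(ca, 2, ctr)^2)))
}

#' Binary C-alpha contact matrix
#'
#' Entry (i, j) is 1 iff the C-alpha distance is strictly below `cutoff`
#' and |i - j| >= 2; the matrix is symmetric with zero diagonal and zero
#' first off-diagonals.
#'
#' @param structure an `hx_structure`.
#' @param cutoff contact distance in Angstrom (default 10, strict `<`).
#' @return integer matrix (residues x residues).
#' @export
contact_matrix <- function(structure, cutoff = 10) {
  ca <- structure$ca
  d <- as.matrix(stats::dist(ca))
  m <- (d < cutoff) * 1L
  nres <- nrow(m)
  ij <- abs(outer(seq_len(nres), seq_len(nres), "-"))
  m[ij < 2] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Extract per-frame HDX features from an ensemble
#'
#' Runs the geometric feature pipeline on every frame: per-site H-bond
#' score (best acceptor over |i-j| >= 2), backbone and side-chain burial
#' levels at the amide H, the total backbone H-bond count, and the
#' radius of gyration. Sites are the exchange-competent amides (no
#' N-terminus, no proline), identified by residue_index.
#'
#' @param ensemble an `hx_ensemble`.
#' @param hbond_made threshold for counting an H-bond as formed.
#' @param burial_cutoff burial switch midpoint in Angstrom.
#' @return object of class `hx_features`; see [frame_features_obj()].
#' @export
frame_features <- function(ensemble, hbond_made = 0.5, burial_cutoff = 6.5) {
  frames <- ensemble$frames
  nf <- length(frames)
  sites <- hdx_sites(frames[[1]])
  res_idx <- frames[[1]]$residue_index[sites]
  ns <- length(sites)
  hb <- matrix(NA_real_, nf, ns)
  bb <- matrix(NA_real_, nf, ns)
  sc <- matrix(NA_real_, nf, ns)
  nhb <- integer(nf)
  rg <- numeric(nf)
  no_sidechains <- is.null(frames[[1]]$sc)
  for (f in seq_len(nf)) {
    st <- frames[[f]]
    sm <- hbond_score_matrix(st)
    hb[f, ] <- apply(sm, 1, function(r)
      if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
    for (k in seq_len(ns)) {
      bl <- burial_level(st, sites[k], cutoff = burial_cutoff)
      bb[f, k] <- bl$bl_bb
      sc[f, k] <- bl$bl_sc
    }
    nhb[f] <- count_hbonds(sm, hbond_made = hbond_made)
    rg[f] <- radius_of_gyration(st)
  }
  if (no_sidechains)
    message("no side-chain centroids in input; bl_sc = 0 for all sites")
  frame_features_obj(residue_index = res_idx, hbond_score = hb,
                     bl_bb = bb, bl_sc = sc, n_hbonds = nhb, rg = rg,
                     weights = ensemble$weights,
                     energies = ensemble$energies)
}

#' Assemble a frame-features object
#'
#' The container shared by the coordinate and feature-table pathways:
#' per-frame, per-site scalars plus per-frame global observables.
#'
#' @param residue_index integer vector of site residue indices.
#' @param hbond_score,bl_bb,bl_sc (frames x sites) matrices.
#' @param n_hbonds integer per-frame backbone H-bond count.
#' @param rg per-frame radius of gyration (Angstrom).
#' @param weights nonnegative per-frame weights (default 1).
#' @param energies optional (frames x states) energy matrix.
#' @return object of class `hx_features`.
#' @export
frame_features_obj <- function(residue_index, hbond_score, bl_bb, bl_sc,
                               n_hbonds = NULL, rg = NULL, weights = NULL,
                               energies = NULL) {
  hbond_score <- as.matrix(hbond_score)
  nf <- nrow(hbond_score); ns <- ncol(hbond_score)
  if (length(residue_index) != ns)
    stop("residue_index length must match the site dimension")
  chk <- function(m, what) {
    m <- as.matrix(m)
    if (!identical(dim(m), c(nf, ns)))
      stop(what, " must be a ", nf, " x ", ns, " matrix")
    m
  }
  bl_bb <- chk(bl_bb, "bl_bb"); bl_sc <- chk(bl_sc, "bl_sc")
  if (any(hbond_score < -1e-9 | hbond_score > 1 + 1e-9, na.rm = TRUE))
    stop("hbond_score must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, nf)
  if (length(weights) != nf || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  if (!is.null(n_hbonds) && length(n_hbonds) != nf)
    stop("n_hbonds must have one value per frame")
  if (!is.null(rg) && length(rg) != nf)
    stop("rg must have one value per frame")
  structure(list(residue_index = as.integer(residue_index),
                 hbond_score = hbond_score, bl_bb = bl_bb, bl_sc = bl_sc,
                 n_hbonds = if (is.null(n_hbonds)) NULL else
                   as.integer(round(n_hbonds)),
                 rg = rg, weights = as.numeric(weights),
                 energies = energies),
            class = "hx_features")
}

#' @export
print.hx_features <- function(x, ...) {
  cat("hx_features:", nrow(x$hbond_score), "frames x",
      ncol(x$hbond_score), "sites\n")
  invisible(x)
}
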
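# Macrostate assignment (native / intermediate / denatured) and the
# trajectory-truncation protocol for irreversibly folding proteins.

#' Native hydrogen-bond reference set
#'
#' All donor -> acceptor backbone H-bond pairs formed in a reference
#' (native) structure, used to define the order parameter Q = fraction
#' of native H-bonds formed.
#'
#' @param native an `hx_structure`.
#' @param hbond_made score threshold for a formed bond (default 0.5).
#' @return data.frame with columns `donor` (residue position) and
#'   `acceptor`.
#' @export
native_hbond_reference <- function(native, hbond_made = 0.5) {
  sm <- hbond_score_matrix(native)
  sites <- attr(sm, "sites")
  idx <- which(sm >= hbond_made, arr.ind = TRUE)
  if (!nrow(idx))
    stop("reference error: no hydrogen bonds found in the native structure")
  data.frame(donor = sites[idx[, 1]], acceptor = as.integer(idx[, 2]))
}

#' Fraction of native hydrogen bonds formed
#'
#' @param structure an `hx_structure` frame.
#' @param reference data.frame from [native_hbond_reference()].
#' @param hbond_made score threshold for a formed bond.
#' @return Q in [0, 1].
#' @export
q_native <- function(structure, reference, hbond_made = 0.5) {
  sm <- hbond_score_matrix(structure)
  sites <- attr(sm, "sites")
  formed <- mapply(function(d, a) {
    k <- match(d, sites)
    !is.na(k) && !is.na(sm[k, a]) && sm[k, a] >= hbond_made
  }, reference$donor, reference$acceptor)
  mean(formed)
}

#' Assign macrostate labels from an order-parameter trace
#'
#' Frames are labelled native ("N") when Q >= `qn`, denatured ("D")
#' when Q <= `qd`, intermediate ("I") otherwise. Labels depend only on
#' the instantaneous Q (no hysteresis).
#'
#' @param q per-frame order parameter in [0, 1] (fraction of native
#'   H-bonds formed).
#' @param qn native threshold (default 0.8).
#' @param qd denatured threshold (default 0.2).
#' @return object of class `hx_macrostates`: list with `labels`, `q`,
#'   `qn`, `qd`.
#' @export
assign_macrostates <- function(q, qn = 0.8, qd = 0.2) {
  if (qn <= qd) stop("configuration error: need qn > qd")
  if (any(q < 0 | q > 1)) stop("Q must lie in [0, 1]")
  labels <- ifelse(q >= qn, "N", ifelse(q <= qd, "D", "I"))
  structure(list(labels = labels, q = q, qn = qn, qd = qd),
            class = "hx_macrostates")
}

#' Truncate an irreversibly folding trajectory
#'
#' For proteins whose unfolded state misfolds instead of refolding, a
#' trajectory started in the native state is only informative up to its
#' first unfolding: frames are kept from the start through the first
#' denatured (D) dwell, and discarded from the first frame after that
#' dwell where the chain leaves D (the refolding attempt). If D is
#' never reached the whole trajectory is kept. The resulting inclusion
#' mask is always a contiguous prefix. Because the denatured state is
#' under-sampled by construction, estimates on truncated traces can
#' overstate native stability; the mask metadata records that the
#' first-exit-from-D rule was applied.
#'
#' @param trace an `hx_macrostates` or a character vector of labels in
#'   {"N", "I", "D"}.
#' @return logical inclusion mask, with attribute `rule` =
#'   "first-exit-from-D".
#' @export
truncate_irreversible <- function(trace) {
  labels <- if (inherits(trace, "hx_macrostates")) trace$labels else trace
  nf <- length(labels)
  if (nf < 1) stop("empty trajectory")
  if (labels[1] != "N")
    stop("protocol error: trajectory must begin in the native state")
  first_d <- match("D", labels)
  if (is.na(first_d)) {
    mask <- rep(TRUE, nf)
  } else {
    after <- which(seq_len(nf) > first_d & labels != "D")
    cut <- if (length(after)) min(after) else nf + 1L
    mask <- seq_len(nf) < cut
  }
  attr(mask, "rule") <- "first-exit-from-D"
  mask
}
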
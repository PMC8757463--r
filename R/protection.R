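# Per-frame protection states and weighted exchange free energies.

#' Protection state of an amide in one frame
#'
#' An NH is protected (PS = 1) when it is either H-bonded (score at or
#' above `hbond_made`) or buried with a total burial level strictly
#' greater than `burial_gt`; otherwise PS = 0. This is the
#' implicit-solvent adaptation of the exchange-competence criterion: a
#' broken but deeply buried amide is still shielded from solvent.
#'
#' @param hbond_score H-bond score in [0, 1] (bimodal; may be vectors).
#' @param bl_total total burial level `bl_bb + 5 * bl_sc`.
#' @param hbond_made H-bond threshold (default 0.5).
#' @param burial_gt burial threshold, strict `>` (default 5).
#' @return 0/1 integer (vectorised).
#' @export
protection_state <- function(hbond_score, bl_total, hbond_made = 0.5,
                             burial_gt = 5) {
  stopifnot(all(is.finite(hbond_score)), all(is.finite(bl_total)))
  as.integer(hbond_score >= hbond_made | bl_total > burial_gt)
}

#' Assemble a protection matrix object
#'
#' @param ps (frames x sites) 0/1 matrix of protection states.
#' @param weights nonnegative per-frame weights with positive sum.
#' @param temperature_K temperature in Kelvin.
#' @param residue_index integer residue indices of the site columns.
#' @return object of class `hx_protection`, carrying `n_protected`
#'   (per-frame protected-NH count, the quantity driving denaturant
#'   reweighting).
#' @export
protection_matrix_obj <- function(ps, weights = NULL, temperature_K = 300,
                                  residue_index = NULL) {
  ps <- as.matrix(ps)
  if (!all(ps %in% c(0, 1))) stop("protection states must be 0/1")
  storage.mode(ps) <- "integer"
  nf <- nrow(ps)
  if (is.null(weights)) weights <- rep(1, nf)
  if (length(weights) != nf || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative, one per frame, with positive sum")
  if (is.null(residue_index)) residue_index <- seq_len(ncol(ps))
  if (length(residue_index) != ncol(ps))
    stop("residue_index must have one entry per site")
  structure(list(ps = ps, weights = as.numeric(weights),
                 n_protected = as.integer(rowSums(ps)),
                 temperature_K = temperature_K,
                 residue_index = as.integer(residue_index)),
            class = "hx_protection")
}

#' @export
print.hx_protection <- function(x, ...) {
  cat("hx_protection:", nrow(x$ps), "frames x", ncol(x$ps), "sites, T =",
      x$temperature_K, "K\n")
  invisible(x)
}

#' Protection matrix from frame features
#'
#' @param features an `hx_features` object.
#' @param temperature_K temperature in Kelvin.
#' @param hbond_made,burial_gt thresholds, see [protection_state()].
#' @return an `hx_protection`.
#' @export
protection_matrix <- function(features, temperature_K = 300,
                              hbond_made = 0.5, burial_gt = 5) {
  stopifnot(inherits(features, "hx_features"))
  bl <- features$bl_bb + 5 * features$bl_sc
  ps <- matrix(protection_state(features$hbond_score, bl,
                                hbond_made, burial_gt),
               nrow(features$hbond_score), ncol(features$hbond_score))
  protection_matrix_obj(ps, weights = features$weights,
                        temperature_K = temperature_K,
                        residue_index = features$residue_index)
}

#' Weighted exchange free energy of one site
#'
#' The EX2 estimator: the opening equilibrium constant is the weighted
#' open/closed ratio, K_op = sum(w * (1 - PS)) / sum(w * PS), and
#' dG_HX = -RT * ln(K_op). Positive values mean net protection. When a
#' site is never observed open (or never closed) the estimate is
#' censored: a one-sided bound is reported instead of an infinity,
#' because rare openings may simply be absent at finite sampling. The
#' bound convention treats the unobserved class as having weight below
#' 1, giving dG >= RT * ln(sum(w * PS)) for a never-open site (and the
#' mirrored upper bound -RT * ln(sum(w * (1 - PS))) for a never-closed
#' site).
#'
#' @param ps_column 0/1 protection states, one per frame.
#' @param weights nonnegative per-frame weights, positive sum.
#' @param temperature_K temperature in Kelvin.
#' @return list with `dG` (kcal mol^-1; the bound when censored),
#'   `f_protected`, `censored` (logical) and `bound` ("none", "lower",
#'   "upper").
#' @export
delta_g_hx <- function(ps_column, weights = NULL, temperature_K = 300) {
  ps <- as.numeric(ps_column)
  if (!all(ps %in% c(0, 1))) stop("protection states must be 0/1")
  if (is.null(weights)) weights <- rep(1, length(ps))
  if (length(weights) != length(ps) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  rt <- rt_kcal(temperature_K)
  w_closed <- sum(weights * ps)
  w_open <- sum(weights * (1 - ps))
  f_prot <- w_closed / (w_closed + w_open)
  if (w_open == 0)
    return(list(dG = -rt * log(1 / w_closed), f_protected = f_prot,
                censored = TRUE, bound = "lower"))
  if (w_closed == 0)
    return(list(dG = rt * log(1 / w_open), f_protected = f_prot,
                censored = TRUE, bound = "upper"))
  list(dG = -rt * log(w_open / w_closed), f_protected = f_prot,
       censored = FALSE, bound = "none")
}

#' Bootstrap standard error of dG_HX
#'
#' Standard deviation of the [delta_g_hx()] estimate over `n_boot`
#' weighted resamples of frames. A block bootstrap (`block_len > 1`)
#' resamples contiguous frame blocks, the appropriate scheme for
#' autocorrelated trajectory frames; `block_len = 1` is the i.i.d.
#' bootstrap. Censored resamples are dropped from the spread estimate.
#'
#' @param ps_column 0/1 protection states per frame.
#' @param weights nonnegative per-frame weights.
#' @param temperature_K temperature in Kelvin.
#' @param n_boot number of resamples (>= 1; >= 100 recommended).
#' @param seed RNG seed for reproducibility.
#' @param block_len bootstrap block length in frames (default 1).
#' @return list with `se` (kcal mol^-1, NA when the point estimate is
#'   censored or all resamples are) and `n_censored`.
#' @export
bootstrap_se <- function(ps_column, weights = NULL, temperature_K = 300,
                         n_boot = 200, seed = NULL, block_len = 1L) {
  if (n_boot < 1) stop("n_boot must be a positive integer")
  ps <- as.numeric(ps_column)
  nf <- length(ps)
  if (is.null(weights)) weights <- rep(1, nf)
  point <- delta_g_hx(ps, weights, temperature_K)
  if (point$censored)
    return(list(se = NA_real_, n_censored = n_boot))
  if (!is.null(seed)) set.seed(seed)
  block_len <- max(1L, as.integer(block_len))
  nblocks <- ceiling(nf / block_len)
  vals <- numeric(n_boot)
  cens <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    if (block_len == 1L) {
      idx <- sample.int(nf, nf, replace = TRUE)
    } else {
      starts <- sample.int(nf - block_len + 1L, nblocks, replace = TRUE)
      idx <- as.vector(outer(0:(block_len - 1L), starts, "+"))[seq_len(nf)]
    }
    r <- delta_g_hx(ps[idx], weights[idx], temperature_K)
    vals[b] <- r$dG
    cens[b] <- r$censored
  }
  ok <- !cens
  if (sum(ok) < 2) return(list(se = NA_real_, n_censored = sum(cens)))
  list(se = stats::sd(vals[ok]), n_censored = sum(cens))
}

#' Per-site HDX summary table
#'
#' Runs [delta_g_hx()] and [bootstrap_se()] for every site of a
#' protection matrix and returns the per-site results as a data frame
#' (m-value columns are filled by the denaturant module, see
#' [site_m_values()]).
#'
#' @param pm an `hx_protection`.
#' @param n_boot bootstrap resamples for the standard error (0 skips).
#' @param seed RNG seed for the bootstrap.
#' @param block_len bootstrap block length.
#' @return data.frame with columns residue_index, dG_HX_kcal_mol,
#'   se_dG, f_protected, m_value, m_closed, m_open, opening_class,
#'   censored_flag.
#' @export
site_hdx <- function(pm, n_boot = 200, seed = NULL, block_len = 1L) {
  stopifnot(inherits(pm, "hx_protection"))
  ns <- ncol(pm$ps)
  out <- data.frame(residue_index = pm$residue_index,
                    dG_HX_kcal_mol = NA_real_, se_dG = NA_real_,
                    f_protected = NA_real_, m_value = NA_real_,
                    m_closed = NA_real_, m_open = NA_real_,
                    opening_class = NA_character_,
                    censored_flag = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ns)) {
    r <- delta_g_hx(pm$ps[, k], pm$weights, pm$temperature_K)
    out$dG_HX_kcal_mol[k] <- r$dG
    out$f_protected[k] <- r$f_protected
    out$censored_flag[k] <- r$censored
    if (n_boot > 0 && !r$censored) {
      sk <- if (is.null(seed)) NULL else seed + k
      out$se_dG[k] <- bootstrap_se(pm$ps[, k], pm$weights,
                                   pm$temperature_K, n_boot = n_boot,
                                   seed = sk, block_len = block_len)$se
    }
  }
  out
}
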
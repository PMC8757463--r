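# Denaturant dependence of HDX by conformational reweighting: dG_HX
# isotherms, m-values, the m_closed/m_open decomposition, scale-factor
# calibration and opening-class assignment.

#' Reweight frames at a denaturant concentration
#'
#' Denaturant destabilises each conformation in proportion to its
#' number of protected backbone NHs: frame n acquires
#' ddG_n = s * n_protected_n * den, so its weight becomes
#' w_n * exp(-s * n_protected_n * den / RT). Conformations with more
#' intact structure are penalised more, shifting population toward open
#' states as denaturant increases. Output is renormalised to the input
#' weight sum.
#'
#' @param weights nonnegative per-frame weights.
#' @param n_protected per-frame protected-NH count.
#' @param s scale factor in kcal mol^-1 M^-1 per protected NH (>= 0).
#' @param den denaturant concentration in M (>= 0).
#' @param temperature_K temperature in Kelvin.
#' @return reweighted per-frame weights.
#' @export
reweight_frames <- function(weights, n_protected, s, den,
                            temperature_K = 300) {
  stopifnot(s >= 0, den >= 0, length(weights) == length(n_protected))
  if (s == 0 || den == 0) return(weights)
  rt <- rt_kcal(temperature_K)
  lw <- log(weights) - s * n_protected * den / rt
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(lw)] <- 0
  w * (sum(weights) / sum(w))
}

#' Denaturant-dependence curve of one site
#'
#' Computes dG_HX at each concentration of `den_grid` by reweighting
#' the ensemble ([reweight_frames()]) and re-estimating
#' ([delta_g_hx()]). The local slope is a centered finite difference on
#' the grid; `m_fit` is minus the least-squares slope of dG_HX versus
#' concentration over the fit window (default the lowest 4 non-censored
#' grid points), so that a destabilising denaturant gives m_fit >= 0.
#' Curves are intrinsically nonlinear when the dominant opening route
#' switches with denaturant, which is why the full local-slope profile
#' is reported alongside the single fitted m-value.
#'
#' @param pm an `hx_protection`.
#' @param site site column index (or residue index via `by_residue`).
#' @param s denaturant scale factor (kcal mol^-1 M^-1 per NH).
#' @param den_grid ascending concentrations in M.
#' @param fit_window number of lowest grid points in the linear fit.
#' @param by_residue if TRUE, `site` is a residue_index.
#' @return object of class `hx_den_curve`: list with `den_grid`, `dG`,
#'   `censored`, `local_slope`, `m_fit`, `m_closed`, `m_open` (the
#'   decomposition at the first grid point), `residue_index`.
#' @export
dg_hx_curve <- function(pm, site, s, den_grid, fit_window = 4L,
                        by_residue = FALSE) {
  stopifnot(inherits(pm, "hx_protection"))
  if (length(den_grid) < 1) stop("den_grid must be non-empty")
  if (is.unsorted(den_grid, strictly = TRUE))
    stop("den_grid must be strictly ascending")
  if (by_residue) site <- match(site, pm$residue_index)
  if (is.na(site) || site < 1 || site > ncol(pm$ps))
    stop("site not present in the protection matrix")
  ng <- length(den_grid)
  dg <- numeric(ng); cens <- logical(ng)
  for (g in seq_len(ng)) {
    w <- reweight_frames(pm$weights, pm$n_protected, s, den_grid[g],
                         pm$temperature_K)
    r <- delta_g_hx(pm$ps[, site], w, pm$temperature_K)
    dg[g] <- r$dG
    cens[g] <- r$censored
  }
  # centered finite differences (one-sided at the ends)
  slope <- rep(NA_real_, ng)
  if (ng >= 2) {
    for (g in seq_len(ng)) {
      lo <- max(1L, g - 1L); hi <- min(ng, g + 1L)
      if (!cens[lo] && !cens[hi] && hi > lo)
        slope[g] <- (dg[hi] - dg[lo]) / (den_grid[hi] - den_grid[lo])
    }
  }
  ok <- which(!cens)
  m_fit <- NA_real_
  if (length(ok) >= 2) {
    use <- ok[seq_len(min(fit_window, length(ok)))]
    m_fit <- -unname(stats::coef(stats::lm(dg[use] ~ den_grid[use]))[2])
  }
  dec <- decompose_m(pm, site, s, den_grid[1])
  structure(list(residue_index = pm$residue_index[site],
                 den_grid = den_grid, dG = dg, censored = cens,
                 local_slope = slope, m_fit = m_fit,
                 m_closed = dec$m_closed, m_open = dec$m_open),
            class = "hx_den_curve")
}

#' @export
print.hx_den_curve <- function(x, ...) {
  cat("hx_den_curve: residue", x$residue_index, " m_fit =",
      signif(x$m_fit, 4), "kcal/mol/M\n")
  invisible(x)
}

#' Decompose a site's m-value into closed- and open-state terms
#'
#' Under exponential reweighting the denaturant sensitivity of a site
#' is exactly m = m_closed - m_open with
#' m_closed = s * <n_protected | site closed> and
#' m_open = s * <n_protected | site open>, the averages taken with the
#' weights reweighted to concentration `den`. A small m-value therefore
#' signals an opening that breaks few protections: the open
#' sub-ensemble remains nearly as structured as the closed one.
#'
#' @param pm an `hx_protection`.
#' @param site site column index.
#' @param s scale factor (kcal mol^-1 M^-1 per NH).
#' @param den concentration in M at which to evaluate.
#' @return list with `m_closed`, `m_open`, `m` (all NA and
#'   `censored = TRUE` when either sub-ensemble is empty).
#' @export
decompose_m <- function(pm, site, s, den = 0) {
  stopifnot(inherits(pm, "hx_protection"))
  w <- reweight_frames(pm$weights, pm$n_protected, s, den,
                       pm$temperature_K)
  ps <- pm$ps[, site]
  np <- pm$n_protected
  w_cl <- w[ps == 1]; n_cl <- np[ps == 1]
  w_op <- w[ps == 0]; n_op <- np[ps == 0]
  if (!length(w_cl) || !length(w_op) || sum(w_cl) == 0 || sum(w_op) == 0)
    return(list(m_closed = NA_real_, m_open = NA_real_, m = NA_real_,
                censored = TRUE))
  m_closed <- s * sum(w_cl * n_cl) / sum(w_cl)
  m_open <- s * sum(w_op * n_op) / sum(w_op)
  list(m_closed = m_closed, m_open = m_open, m = m_closed - m_open,
       censored = FALSE)
}

#' Calibrate the denaturant scale factor against an experimental m-value
#'
#' Solves for the scale factor s such that the fitted m-value of a
#' reference site (the site exchanging with the largest protection
#' change, normally a globally exchanging amide) reproduces the
#' experimental global m-value. In the strict two-state limit the
#' solution is s = m_global / delta_n_protected; in general a 1-D root
#' find is used.
#'
#' @param pm an `hx_protection`.
#' @param reference_site site column index of the calibration site.
#' @param experimental_m_global experimental m-value (kcal mol^-1 M^-1,
#'   > 0).
#' @param den_grid concentrations used for the internal m_fit (default
#'   0 to 1.5 M).
#' @param fit_window fit window passed to [dg_hx_curve()].
#' @param interval search interval for s.
#' @param tol root tolerance on s.
#' @return calibrated s (kcal mol^-1 M^-1 per protected NH).
#' @export
calibrate_s <- function(pm, reference_site, experimental_m_global,
                        den_grid = seq(0, 1.5, by = 0.5),
                        fit_window = 4L, interval = c(1e-8, 10),
                        tol = 1e-10) {
  if (!is.finite(experimental_m_global) || experimental_m_global <= 0)
    stop("experimental m-value must be positive")
  fn <- function(s)
    dg_hx_curve(pm, reference_site, s, den_grid,
                fit_window = fit_window)$m_fit - experimental_m_global
  flo <- fn(interval[1]); fhi <- fn(interval[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("calibration failure: no sign change for s in [",
         interval[1], ", ", interval[2], "]; f(lo) = ", signif(flo, 4),
         ", f(hi) = ", signif(fhi, 4),
         " (is the reference site censored, or m too large?)")
  stats::uniroot(fn, interval, tol = tol)$root
}

#' Classify an opening by its denaturant sensitivity
#'
#' Openings are classified by the ratio of a site's m-value to the
#' global m-value: near-zero sensitivity means a local opening (a few
#' H-bonds broken), full sensitivity means exchange through global
#' unfolding, and intermediate ratios mark subglobal openings
#' (foldon-scale units).
#'
#' @param m_fit site m-value (kcal mol^-1 M^-1); NA gives "unresolved".
#' @param m_global global m-value (> 0).
#' @param local_max ratio below which the opening is "local" (0.15).
#' @param global_min ratio at or above which it is "global" (0.80).
#' @return character class: "local", "subglobal", "global" or
#'   "unresolved" (vectorised over `m_fit`).
#' @export
classify_opening <- function(m_fit, m_global, local_max = 0.15,
                             global_min = 0.80) {
  if (!is.finite(m_global) || m_global <= 0)
    stop("m_global must be positive")
  r <- m_fit / m_global
  out <- ifelse(is.na(r), "unresolved",
                ifelse(r < local_max, "local",
                       ifelse(r < global_min, "subglobal", "global")))
  out
}

#' Fill m-values and opening classes into a site table
#'
#' Convenience wrapper running [dg_hx_curve()] for every site and
#' adding m_value, m_closed, m_open and opening_class columns to the
#' output of [site_hdx()].
#'
#' @param sites data.frame from [site_hdx()].
#' @param pm the `hx_protection` the table was computed from.
#' @param s denaturant scale factor.
#' @param den_grid concentrations in M.
#' @param m_global global m-value for classification (default: the
#'   maximum finite m_fit across sites).
#' @param fit_window fit window for the linear m fit.
#' @return the site table with m columns filled.
#' @export
site_m_values <- function(sites, pm, s, den_grid,
                          m_global = NULL, fit_window = 4L) {
  ns <- ncol(pm$ps)
  stopifnot(nrow(sites) == ns)
  for (k in seq_len(ns)) {
    cv <- dg_hx_curve(pm, k, s, den_grid, fit_window = fit_window)
    sites$m_value[k] <- cv$m_fit
    sites$m_closed[k] <- cv$m_closed
    sites$m_open[k] <- cv$m_open
  }
  if (is.null(m_global)) {
    mg <- suppressWarnings(max(sites$m_value, na.rm = TRUE))
    if (!is.finite(mg) || mg <= 0) {
      sites$opening_class <- "unresolved"
      return(sites)
    }
    m_global <- mg
  }
  sites$opening_class <- classify_opening(sites$m_value, m_global)
  sites
}
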
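# Linderstrom-Lang exchange kinetics: observed rates, EX1/EX2
# diagnostics, protection factors, multi-pathway flux.

#' Observed exchange rate through a single opening
#'
#' Steady-state Linderstrom-Lang rate for the scheme
#' closed <-> open -> exchanged:
#' k_obs = k_chem * k_open / (k_close + k_chem). In the EX2 limit
#' (k_close >> k_chem) this reduces to k_chem * K_op; in the EX1 limit
#' (k_close << k_chem) every opening exchanges and k_obs = k_open.
#'
#' @param k_open,k_close,k_chem rates in s^-1 (>= 0).
#' @return k_obs in s^-1.
#' @export
k_obs_single <- function(k_open, k_close, k_chem) {
  stopifnot(k_open >= 0, k_close >= 0, k_chem >= 0)
  if (k_close + k_chem == 0)
    stop("undefined rate: k_close + k_chem must be positive")
  k_chem * k_open / (k_close + k_chem)
}

#' Observed exchange rate through multiple EX2 pathways
#'
#' A site able to open locally, subglobally and globally exchanges with
#' the summed flux of all routes. Assuming EX2 for each pathway j with
#' opening free energy dG_j and denaturant sensitivity m_j,
#' k_obs(den) = k_chem * sum_j exp(-(dG_j - m_j * den) / RT). The
#' effective dG_HX = -RT * ln(k_obs / k_chem) is then a log-sum-exp
#' over routes and is dominated by the lowest-energy opening at each
#' concentration; as denaturant preferentially stabilises the larger
#' openings, the dominant route (and the apparent m-value) shifts from
#' local toward global.
#'
#' @param dG_open per-pathway opening free energies, kcal mol^-1.
#' @param m_open_pathway per-pathway m-values, kcal mol^-1 M^-1.
#' @param den denaturant concentration in M.
#' @param k_chem intrinsic chemical exchange rate, s^-1 (> 0).
#' @param temperature_K temperature in Kelvin.
#' @return k_obs in s^-1.
#' @export
k_obs_multipathway <- function(dG_open, m_open_pathway, den, k_chem,
                               temperature_K = 300) {
  stopifnot(k_chem > 0, length(dG_open) == length(m_open_pathway),
            den >= 0)
  rt <- rt_kcal(temperature_K)
  k_chem * exp(logsumexp(-(dG_open - m_open_pathway * den) / rt))
}

#' Effective exchange free energy of a multi-pathway site
#'
#' -RT * ln(k_obs / k_chem) for the flux-summed rate of
#' [k_obs_multipathway()]; always at or below the free energy of the
#' cheapest single route.
#'
#' @inheritParams k_obs_multipathway
#' @return dG_HX in kcal mol^-1.
#' @export
effective_dg_hx <- function(dG_open, m_open_pathway, den,
                            temperature_K = 300) {
  rt <- rt_kcal(temperature_K)
  -rt * logsumexp(-(dG_open - m_open_pathway * den) / rt)
}

#' Effective denaturant slope of a multi-pathway site
#'
#' The analytic -d(dG_eff)/d(den): the flux-weighted average of the
#' per-pathway m-values, rising from the local value toward the global
#' one as the global route takes over.
#'
#' @inheritParams k_obs_multipathway
#' @return effective m in kcal mol^-1 M^-1.
#' @export
effective_m <- function(dG_open, m_open_pathway, den,
                        temperature_K = 300) {
  rt <- rt_kcal(temperature_K)
  lw <- -(dG_open - m_open_pathway * den) / rt
  w <- exp(lw - max(lw))
  sum(w * m_open_pathway) / sum(w)
}

#' EX1/EX2 regime diagnostic
#'
#' Exchange is EX2 (thermodynamic: rates report on equilibrium opening)
#' when closing is much faster than chemistry, and EX1 (kinetic: rates
#' report on opening rates) in the opposite limit.
#'
#' @param k_close closing rate, s^-1.
#' @param k_chem intrinsic chemical rate, s^-1.
#' @param ratio_threshold regime boundary on k_close/k_chem (default
#'   10: at or above gives EX2, at or below 1/10 gives EX1).
#' @return list with `regime` ("EX2", "EX1" or "intermediate"),
#'   `ratio`, and `flagged` (TRUE for the degenerate k_chem = 0 case,
#'   EX2 by convention).
#' @export
ex_regime <- function(k_close, k_chem, ratio_threshold = 10) {
  stopifnot(k_close >= 0, k_chem >= 0, ratio_threshold > 1)
  if (k_chem == 0)
    return(list(regime = "EX2", ratio = Inf, flagged = TRUE))
  r <- k_close / k_chem
  regime <- if (r >= ratio_threshold) "EX2"
            else if (r <= 1 / ratio_threshold) "EX1"
            else "intermediate"
  list(regime = regime, ratio = r, flagged = FALSE)
}

#' Protection factor
#'
#' PF = k_chem / k_obs, the fold-slowing of exchange due to structure.
#' In the EX2 limit RT * ln(PF) equals the exchange free energy of the
#' lowest-energy opening combination.
#'
#' @param k_chem intrinsic chemical rate, s^-1.
#' @param k_obs observed rate, s^-1.
#' @return list with `PF` (Inf and `flagged = TRUE` when k_obs = 0).
#' @export
protection_factor <- function(k_chem, k_obs) {
  stopifnot(k_chem >= 0, k_obs >= 0)
  if (k_obs == 0) return(list(PF = Inf, flagged = TRUE))
  list(PF = k_chem / k_obs, flagged = FALSE)
}
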
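# Free-energy surfaces: weighted 2D histograms, PCA on contact maps,
# and a self-contained MBAR solver for replica-exchange data.

#' Solve the MBAR equations
#'
#' Multistate Bennett acceptance ratio estimate of the reduced free
#' energies f_k of K thermodynamic states from samples drawn at each
#' state. Solves the self-consistent equations
#' f_k = -ln sum_n exp(-u_kn) / sum_l N_l exp(f_l - u_ln)
#' by damped fixed-point iteration with log-sum-exp stabilisation,
#' gauge-fixed at f_1 = 0.
#'
#' @param u_kn (K x N) matrix of reduced energies: u_kn[k, n] is the
#'   energy of frame n evaluated in state k, in units of kT of state k.
#' @param N_k number of frames sampled from each state (sums to N).
#' @param tol convergence tolerance on max |f change| (default 1e-10).
#' @param max_iter iteration cap.
#' @param damping fraction of the new iterate kept per step (0.5).
#' @return object of class `hx_mbar`: list with `f_k`, `log_denom`
#'   (per-frame mixture log-denominator), `iterations`, `residual`,
#'   `overlap_warning` (TRUE when some state has effective sample size
#'   < 2, i.e. essentially no overlap).
#' @export
solve_mbar <- function(u_kn, N_k, tol = 1e-10, max_iter = 100000L,
                       damping = 0.5) {
  u_kn <- as.matrix(u_kn)
  K <- nrow(u_kn); N <- ncol(u_kn)
  if (any(!is.finite(u_kn))) stop("reduced energies must be finite")
  if (length(N_k) != K || sum(N_k) != N)
    stop("N_k must have one entry per state and sum to the frame count")
  logN <- log(N_k)
  f <- numeric(K)
  resid <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    # per-frame log denominator of the mixture distribution
    ld <- apply(logN + f - u_kn, 2, logsumexp)
    f_new <- -apply(-u_kn - rep(ld, each = K), 1, logsumexp)
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- damping * f_new + (1 - damping) * f
    f <- f - f[1]
    if (resid <= tol || it >= max_iter) break
  }
  if (resid > tol)
    stop("MBAR did not converge in ", max_iter,
         " iterations (residual ", signif(resid, 3), ")")
  ld <- apply(logN + f - u_kn, 2, logsumexp)
  # overlap diagnostic: ESS of the weights at each state
  overlap <- FALSE
  for (k in seq_len(K)) {
    lw <- -u_kn[k, ] - ld
    w <- exp(lw - logsumexp(lw))
    if (1 / sum(w^2) < 2) overlap <- TRUE
  }
  if (overlap)
    warning("poor state overlap: some state has effective sample size < 2")
  structure(list(f_k = f, log_denom = ld, u_kn = u_kn, N_k = N_k,
                 iterations = it, residual = resid,
                 overlap_warning = overlap),
            class = "hx_mbar")
}

#' @export
print.hx_mbar <- function(x, ...) {
  cat("hx_mbar:", length(x$f_k), "states,", x$iterations,
      "iterations, residual", signif(x$residual, 3), "\n")
  cat("  f_k:", signif(x$f_k, 6), "\n")
  invisible(x)
}

#' Frame weights at a target thermodynamic state
#'
#' Normalised MBAR weights w_n proportional to
#' exp(-u_target(n)) / sum_l N_l exp(f_l - u_l(n)); with these weights
#' any observable can be averaged as if sampled at the target state.
#' With a single state MBAR reduces to uniform weights.
#'
#' @param sol an `hx_mbar` solution.
#' @param u_target per-frame reduced energies in the target state;
#'   defaults to state 1 of the solution.
#' @return numeric weights summing to 1.
#' @export
mbar_weights <- function(sol, u_target = NULL) {
  stopifnot(inherits(sol, "hx_mbar"))
  if (is.null(u_target)) u_target <- sol$u_kn[1, ]
  lw <- -u_target - sol$log_denom
  w <- exp(lw - logsumexp(lw))
  w / sum(w)
}

#' Weighted two-dimensional free-energy surface
#'
#' Bins frames on two collective variables, converts the weighted
#' probability mass per bin to a free energy -RT * ln(p), and shifts
#' the minimum over occupied bins to zero. Empty bins are reported as
#' NA (unoccupied), never as numeric infinities.
#'
#' @param x,y per-frame collective variables (e.g. Rg and H-bond
#'   count, or PC1 and PC2).
#' @param weights nonnegative per-frame weights (default uniform).
#' @param bins number of bins per axis (length 1 or 2), or a list of
#'   two explicit bin-edge vectors.
#' @param temperature_K temperature in Kelvin.
#' @param axes character names of the two axes.
#' @return object of class `hx_fes`: list with `x_edges`, `y_edges`,
#'   `prob` (bin probability mass), `free_energy` (kcal mol^-1, NA for
#'   empty bins), `axes`, `total_weight`.
#' @export
fes_2d <- function(x, y, weights = NULL, bins = 25,
                   temperature_K = 300, axes = c("x", "y")) {
  stopifnot(length(x) == length(y))
  nf <- length(x)
  if (nf < 1) stop("need at least one frame")
  if (is.null(weights)) weights <- rep(1, nf)
  stopifnot(length(weights) == nf, all(weights >= 0), sum(weights) > 0)
  edges <- function(v, nb) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = nb + 1)
  }
  if (is.list(bins)) {
    xe <- bins[[1]]; ye <- bins[[2]]
  } else {
    if (length(bins) == 1) bins <- c(bins, bins)
    if (any(bins < 2)) stop("need at least 2 bins per axis")
    xe <- edges(x, bins[1]); ye <- edges(y, bins[2])
  }
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  nbx <- length(xe) - 1; nby <- length(ye) - 1
  mass <- matrix(0, nbx, nby)
  for (f in seq_len(nf))
    mass[ix[f], iy[f]] <- mass[ix[f], iy[f]] + weights[f]
  prob <- mass / sum(mass)
  fe <- matrix(NA_real_, nbx, nby)
  occ <- prob > 0
  rt <- rt_kcal(temperature_K)
  fe[occ] <- -rt * log(prob[occ])
  fe <- fe - min(fe, na.rm = TRUE)
  structure(list(x_edges = xe, y_edges = ye, prob = prob,
                 free_energy = fe, axes = axes,
                 total_weight = sum(weights)),
            class = "hx_fes")
}

#' @export
print.hx_fes <- function(x, ...) {
  cat("hx_fes:", length(x$x_edges) - 1, "x", length(x$y_edges) - 1,
      "bins on (", x$axes[1], ",", x$axes[2], "); max barrier",
      signif(max(x$free_energy, na.rm = TRUE), 4), "kcal/mol\n")
  invisible(x)
}

#' Weighted PCA on per-frame contact matrices
#'
#' Flattens each frame's binary C-alpha contact matrix (entries with
#' |i-j| >= 2, upper triangle) into a feature vector, centers with the
#' weighted mean, and decomposes the weighted covariance. Component
#' signs are fixed by making the largest-magnitude loading positive,
#' so projections are reproducible across runs. Frame projections on
#' (PC1, PC2) are the usual axes for folding-route free-energy
#' surfaces.
#'
#' @param contact_list list of (residues x residues) contact matrices,
#'   one per frame.
#' @param weights nonnegative per-frame weights (default uniform);
#'   use MBAR or denaturant weights to center the decomposition on a
#'   target thermodynamic state.
#' @param n_components number of components to return.
#' @return list with `components` (features x n_components loadings),
#'   `variance` (per-component explained variance), `projections`
#'   (frames x n_components), `degenerate` (TRUE when total variance
#'   is zero).
#' @export
pca_contacts <- function(contact_list, weights = NULL, n_components = 2L) {
  nf <- length(contact_list)
  if (nf < 2) stop("need at least 2 frames")
  dims <- dim(contact_list[[1]])
  if (!all(vapply(contact_list, function(m) identical(dim(m), dims),
                  logical(1))))
    stop("all contact matrices must share one shape")
  keep <- upper.tri(contact_list[[1]]) &
    abs(row(contact_list[[1]]) - col(contact_list[[1]])) >= 2
  X <- t(vapply(contact_list, function(m) as.numeric(m[keep]),
                numeric(sum(keep))))
  if (is.null(weights)) weights <- rep(1, nf)
  stopifnot(length(weights) == nf, all(weights >= 0), sum(weights) > 0)
  wn <- weights / sum(weights)
  mu <- colSums(X * wn)
  Xc <- sweep(X, 2, mu)
  sv <- svd(sqrt(wn) * Xc)
  var_all <- sv$d^2
  degenerate <- sum(var_all) < 1e-12
  nc <- min(n_components, length(var_all))
  comp <- sv$v[, seq_len(nc), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(nc)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  proj <- Xc %*% comp
  if (degenerate) proj[] <- 0
  list(components = comp, variance = var_all[seq_len(nc)],
       projections = proj, degenerate = degenerate)
}
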
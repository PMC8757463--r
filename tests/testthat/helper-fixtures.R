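# Shared fixtures and small independent oracles used across tests.

# random proper rotation matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid isometry to every coordinate block of a structure
transform_structure <- function(st, rot, shift = c(0, 0, 0)) {
  tr <- function(m) {
    if (is.null(m)) return(NULL)
    ok <- stats::complete.cases(m)
    m[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(rot), 2, -shift)
    m
  }
  st$n <- tr(st$n); st$ca <- tr(st$ca); st$c <- tr(st$c); st$o <- tr(st$o)
  st$h <- tr(st$h); st$sc <- tr(st$sc)
  st
}

# minimal structure with prescribed CA positions (N, C, O offset nearby);
# enough for contact-matrix and Rg tests
structure_from_ca <- function(ca) {
  ca <- as.matrix(ca)
  nres <- nrow(ca)
  hx_structure(residue_index = seq_len(nres), residue_name = "ALA",
               n = sweep(ca, 2, c(-1.2, 0.3, 0)),
               ca = ca,
               c = sweep(ca, 2, c(1.3, 0.4, 0)),
               o = sweep(ca, 2, c(1.8, 1.4, 0)))
}

# strict two-state model: native vs unfolded
two_state_model <- function(n_sites = 30, dG = 5, temperature_K = 300,
                            eps_unfolded = NULL) {
  unf <- list(name = "unfolded", G = dG, template = rep(0, n_sites))
  if (!is.null(eps_unfolded)) unf$eps <- eps_unfolded
  state_model(list(
    list(name = "native", G = 0, template = rep(1, n_sites)),
    unf), n_sites, temperature_K)
}

# model with a site-resolved opening hierarchy: site 2 opens locally,
# sites 1-10 open subglobally, sites 11-30 only in the unfolded state
hierarchy_model <- function(dG_local = 2, dG_subglobal = 5,
                            dG_global = 8, temperature_K = 300) {
  n <- 30
  t_local <- rep(1, n); t_local[2] <- 0
  t_sub <- rep(1, n); t_sub[1:10] <- 0
  state_model(list(
    list(name = "native", G = 0, template = rep(1, n)),
    list(name = "local_2", G = dG_local, template = t_local),
    list(name = "subglobal_1", G = dG_subglobal, template = t_sub),
    list(name = "unfolded", G = dG_global, template = rep(0, n))),
    n, temperature_K)
}

# dG_HX of one site at a denaturant concentration, through the
# reweight + estimate pipeline (the implementation path under test)
pipeline_dg <- function(pm, site, s, den) {
  w <- reweight_frames(pm$weights, pm$n_protected, s, den,
                       pm$temperature_K)
  delta_g_hx(pm$ps[, site], w, pm$temperature_K)$dG
}

# tight centered finite-difference slope of the pipeline dG_HX curve
fd_slope <- function(pm, site, s, den, h = 1e-4) {
  (pipeline_dg(pm, site, s, den + h) -
     pipeline_dg(pm, site, s, max(0, den - h))) /
    (den + h - max(0, den - h))
}

# write a minimal CHARMM-format DCD file (used to test the DCD reader)
write_minimal_dcd <- function(path, coords_list) {
  natom <- nrow(coords_list[[1]])
  nfr <- length(coords_list)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(write_payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    write_payload()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- formatC("minimal dcd fixture", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natom), con, size = 4), 4)
  for (xyz in coords_list) {
    for (ax in 1:3)
      rec(function() writeBin(as.numeric(xyz[, ax]), con, size = 4),
          4 * natom)
  }
  invisible(path)
}
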
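# Reading conformational ensembles and feature tables; writing per-site
# results and free-energy grids; run configuration.

backbone_names <- c("N", "CA", "C", "O")

# build one hx_structure from a bio3d atom table plus one xyz row
structure_from_atoms <- function(atom, xyz_row) {
  coords <- matrix(xyz_row, ncol = 3, byrow = TRUE)
  key <- paste(atom$chain, atom$resno)
  resk <- unique(key)
  nres <- length(resk)
  res_idx <- atom$resno[match(resk, key)]
  res_name <- atom$resid[match(resk, key)]
  chain <- atom$chain[match(resk, key)][1]
  if (is.na(chain)) chain <- "A"
  get_mat <- function(elety) {
    m <- matrix(NA_real_, nres, 3)
    sel <- which(atom$elety == elety)
    r <- match(key[sel], resk)
    m[r, ] <- coords[sel, , drop = FALSE]
    m
  }
  N <- get_mat("N"); CA <- get_mat("CA"); C <- get_mat("C"); O <- get_mat("O")
  hsel <- which(atom$elety %in% c("H", "HN"))
  H <- NULL
  if (length(hsel)) {
    H <- matrix(NA_real_, nres, 3)
    H[match(key[hsel], resk), ] <- coords[hsel, , drop = FALSE]
  }
  # side-chain centroid: heavy atoms beyond the backbone
  scsel <- which(!(atom$elety %in% c(backbone_names, "OXT")) &
                   !grepl("^[0-9]*H", atom$elety))
  SC <- NULL
  if (length(scsel)) {
    SC <- matrix(NA_real_, nres, 3)
    for (r in unique(match(key[scsel], resk))) {
      rows <- scsel[match(key[scsel], resk) == r]
      SC[r, ] <- colMeans(coords[rows, , drop = FALSE])
    }
  }
  # every residue except chain termini must have a full backbone
  interior <- seq_len(nres)
  bad <- vapply(interior, function(r)
    any(!is.finite(c(N[r, ], CA[r, ], C[r, ]))) ||
      (r < nres && any(!is.finite(O[r, ]))), logical(1))
  bad[c(1, nres)] <- vapply(c(1, nres), function(r)
    any(!is.finite(CA[r, ])), logical(1))
  if (any(bad))
    stop("frame rejected: missing backbone atoms at residue(s) ",
         paste(res_idx[bad], collapse = ", "))
  if (any(!is.finite(O[nres, ]))) O[nres, ] <- C[nres, ]  # terminal OXT-only
  hx_structure(residue_index = res_idx, residue_name = res_name,
               n = N, ca = CA, c = C, o = O, h = H, sc = SC,
               chain = chain)
}

#' Read a conformational ensemble from trajectory files
#'
#' Supported inputs: a multi-model PDB (one frame per MODEL), or a DCD
#' trajectory with a PDB topology. Residue numbering and frame order
#' are preserved from the input. Frames with missing backbone atoms at
#' non-terminal residues are rejected with an error rather than
#' silently skipped, since silent frame loss biases the exchange free
#' energies.
#'
#' @param trajectory path to a multi-model PDB or a DCD file.
#' @param topology path to a PDB topology (required for DCD).
#' @param weights optional per-frame weights.
#' @return an `hx_ensemble`.
#' @export
read_ensemble <- function(trajectory, topology = NULL, weights = NULL) {
  if (!file.exists(trajectory)) stop("file not found: ", trajectory)
  ext <- tolower(tools::file_ext(trajectory))
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(trajectory, multi = TRUE)
    atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    sel <- as.vector(t(outer(3 * (as.integer(rownames(atom)) - 1L), 1:3, "+")))
    frames <- lapply(seq_len(nrow(xyz)), function(f)
      structure_from_atoms(atom, xyz[f, sel]))
  } else if (ext == "dcd") {
    if (is.null(topology))
      stop("a PDB topology is required to read a DCD trajectory")
    top <- bio3d::read.pdb(topology)
    atom <- top$atom[top$atom$type == "ATOM", , drop = FALSE]
    xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3 * nrow(atom))
      stop("consistency error: topology has ", nrow(atom),
           " atoms but trajectory frames have ", ncol(xyz) / 3)
    frames <- lapply(seq_len(nrow(xyz)), function(f)
      structure_from_atoms(atom, xyz[f, ]))
  } else if (ext == "xtc") {
    stop("XTC input is not supported; convert to DCD or multi-model PDB")
  } else {
    stop("unrecognised trajectory format: .", ext)
  }
  if (!length(frames)) stop("empty input: no frames read")
  hx_ensemble(frames, weights = weights)
}

#' Write an ensemble as a multi-model PDB
#'
#' Backbone atoms (N, CA, C, O) plus any explicit amide hydrogens and
#' side-chain centroids (as CB pseudo-atoms) are written, one MODEL per
#' frame.
#'
#' @param ensemble an `hx_ensemble`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00"
  for (f in seq_along(ensemble$frames)) {
    st <- ensemble$frames[[f]]
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (r in seq_along(st$residue_index)) {
      emit <- function(name, xyz) {
        if (any(!is.finite(xyz))) return()
        serial <<- serial + 1L
        nm <- if (nchar(name) < 4) paste0(" ", name) else name
        writeLines(sprintf(fmt, serial, nm, st$residue_name[r], st$chain,
                           st$residue_index[r], xyz[1], xyz[2], xyz[3]),
                   con)
      }
      emit("N", st$n[r, ]); emit("CA", st$ca[r, ])
      emit("C", st$c[r, ]); emit("O", st$o[r, ])
      if (!is.null(st$h)) emit("H", st$h[r, ])
      if (!is.null(st$sc)) emit("CB", st$sc[r, ])
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a per-frame per-site feature table
#'
#' The tabular alternative to coordinate input: a CSV/TSV with one row
#' per (frame, site) pair. Required columns: `frame`, `site` (residue
#' index of the amide), `hbond_score`, `bl_bb`, `bl_sc`. Optional
#' frame-level columns: `n_hbonds`, `rg`, `weight` (default 1) and any
#' number of `energy_state_<k>` columns for multistate reweighting.
#' The table must be rectangular: every frame carries every site.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @return an `hx_features`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("frame", "site", "hbond_score", "bl_bb", "bl_sc")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  frames <- sort(unique(df$frame))
  sites <- sort(unique(df$site))
  if (nrow(df) != length(frames) * length(sites) ||
      anyDuplicated(df[c("frame", "site")]))
    stop("completeness error: table is not rectangular ",
         "(every frame must carry every site exactly once)")
  fi <- match(df$frame, frames); si <- match(df$site, sites)
  mk <- function(col) {
    m <- matrix(NA_real_, length(frames), length(sites))
    m[cbind(fi, si)] <- df[[col]]
    m
  }
  per_frame <- function(col) {
    if (!col %in% names(df)) return(NULL)
    v <- rep(NA_real_, length(frames))
    v[fi] <- df[[col]]
    v
  }
  w <- per_frame("weight")
  if (!is.null(w) && any(w < 0))
    stop("domain error: negative frame weight")
  ecols <- grep("^energy_state_", names(df), value = TRUE)
  energies <- NULL
  if (length(ecols)) {
    energies <- sapply(ecols, per_frame)
    colnames(energies) <- ecols
  }
  frame_features_obj(residue_index = sites, hbond_score = mk("hbond_score"),
                     bl_bb = mk("bl_bb"), bl_sc = mk("bl_sc"),
                     n_hbonds = per_frame("n_hbonds"),
                     rg = per_frame("rg"), weights = w,
                     energies = energies)
}

#' Write a feature table
#'
#' Long-format CSV/TSV consumable by [read_feature_table()].
#'
#' @param features an `hx_features`.
#' @param path output path (`.csv` or `.tsv`).
#' @return invisibly, the path.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(inherits(features, "hx_features"))
  nf <- nrow(features$hbond_score); ns <- ncol(features$hbond_score)
  df <- data.frame(frame = rep(seq_len(nf), each = ns),
                   site = rep(features$residue_index, times = nf),
                   hbond_score = as.vector(t(features$hbond_score)),
                   bl_bb = as.vector(t(features$bl_bb)),
                   bl_sc = as.vector(t(features$bl_sc)),
                   weight = rep(features$weights, each = ns))
  if (!is.null(features$n_hbonds))
    df$n_hbonds <- rep(features$n_hbonds, each = ns)
  if (!is.null(features$rg)) df$rg <- rep(features$rg, each = ns)
  if (!is.null(features$energies))
    for (k in seq_len(ncol(features$energies)))
      df[[paste0("energy_state_", k)]] <-
        rep(features$energies[, k], each = ns)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write per-site HDX results
#'
#' CSV with one row per site; numeric values survive a write/read
#' round-trip to at least 6 significant figures.
#'
#' @param results data.frame from [site_hdx()] / [site_m_values()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_site_results <- function(results, path) {
  if (!is.data.frame(results) || !nrow(results))
    stop("empty input: no site results to write")
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-site HDX results
#'
#' @param path CSV written by [write_site_results()].
#' @return data.frame.
#' @export
read_site_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise a free-energy grid to JSON
#'
#' @param grid an `hx_fes`.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_fes_json <- function(grid, path) {
  stopifnot(inherits(grid, "hx_fes"))
  obj <- list(axes = grid$axes, x_edges = grid$x_edges,
              y_edges = grid$y_edges,
              free_energy = grid$free_energy,
              prob = grid$prob, total_weight = grid$total_weight)
  jsonlite::write_json(obj, path, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' Default run configuration
#'
#' Central bundle of the tunable analysis parameters, with the package
#' defaults: T = 300 K, burial threshold 5 (strict >), H-bond-made
#' threshold 0.5 on the bimodal score, denaturant grid 0..6 M.
#'
#' @param temperature_K temperature in Kelvin.
#' @param denaturant_grid ascending concentrations in M.
#' @param scale_factor_s kcal mol^-1 M^-1 per protected NH, or the
#'   string "calibrate".
#' @param hbond_made H-bond threshold.
#' @param burial_cutoff_BL burial threshold (strict `>`).
#' @param fit_window linear-fit window (grid points) for m_fit.
#' @param local_max,global_min opening-class thresholds on m/m_global.
#' @param qn,qd macrostate thresholds on Q.
#' @param seed RNG seed.
#' @return object of class `hx_config` (a named list).
#' @export
run_config <- function(temperature_K = 300,
                       denaturant_grid = seq(0, 6, by = 0.5),
                       scale_factor_s = 0.05,
                       hbond_made = 0.5, burial_cutoff_BL = 5,
                       fit_window = 4L, local_max = 0.15,
                       global_min = 0.80, qn = 0.8, qd = 0.2,
                       seed = 1L) {
  if (temperature_K <= 0) stop("temperature must be positive")
  if (is.unsorted(denaturant_grid) || any(denaturant_grid < 0))
    stop("denaturant grid must be ascending and nonnegative")
  if (is.numeric(scale_factor_s) && scale_factor_s < 0)
    stop("scale factor s must be >= 0")
  structure(list(temperature_K = temperature_K,
                 denaturant_grid = denaturant_grid,
                 scale_factor_s = scale_factor_s,
                 hbond_made = hbond_made,
                 burial_cutoff_BL = burial_cutoff_BL,
                 fit_window = fit_window, local_max = local_max,
                 global_min = global_min, qn = qn, qd = qd,
                 seed = seed),
            class = "hx_config")
}

#' Read a JSON run configuration
#'
#' Keys present in the file override the [run_config()] defaults;
#' unknown keys are an error (typo protection).
#'
#' @param path JSON file.
#' @return an `hx_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
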
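test_that("multi-model PDB round-trips frames, residues and numbering", {
  h <- make_helix_fixture(6)
  ens <- hx_ensemble(list(h, transform_structure(h, diag(3), c(5, 0, 0)),
                          transform_structure(h, diag(3), c(0, 5, 0))))
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble(path)
  expect_equal(n_frames(back), 3)
  expect_equal(n_residues(back$frames[[1]]), 6)
  expect_identical(back$frames[[1]]$residue_index, h$residue_index)
  expect_equal(back$frames[[1]]$ca, h$ca, tolerance = 1e-3)
  expect_equal(back$frames[[2]]$ca, h$ca + rep(c(5, 0, 0), each = 6),
               tolerance = 1e-3)
})

test_that("residue numbering offsets survive reading", {
  h <- make_helix_fixture(6)
  h$residue_index <- h$residue_index + 41L  # e.g. a construct numbering
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(hx_ensemble(list(h)), path)
  back <- read_ensemble(path)
  expect_equal(back$frames[[1]]$residue_index[1], 42L)
  expect_equal(back$frames[[1]]$residue_index[6], 47L)
})

test_that("DCD trajectories load against a PDB topology", {
  h <- make_helix_fixture(6)
  top <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(hx_ensemble(list(h)), top)
  atoms_per_res <- 4  # N, CA, C, O as written
  coords <- do.call(rbind, lapply(seq_len(6), function(r)
    rbind(h$n[r, ], h$ca[r, ], h$c[r, ], h$o[r, ])))
  dcd <- tempfile(fileext = ".dcd")
  write_minimal_dcd(dcd, replicate(7, coords, simplify = FALSE))
  ens <- read_ensemble(dcd, topology = top)
  expect_equal(n_frames(ens), 7)
  expect_equal(ens$frames[[1]]$ca, h$ca, tolerance = 1e-5)
  # atom-count mismatch against a larger topology is a consistency error
  top2 <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(hx_ensemble(list(make_helix_fixture(20))), top2)
  expect_error(read_ensemble(dcd, topology = top2), "consistency")
  expect_error(read_ensemble(dcd), "topology")
})

test_that("unreadable inputs produce format errors", {
  expect_error(read_ensemble("does-not-exist.pdb"), "not found")
  p <- tempfile(fileext = ".xtc"); file.create(p)
  expect_error(read_ensemble(p), "XTC")
})

test_that("feature tables round-trip and enforce their schema", {
  h <- make_helix_fixture(8)
  ens <- hx_ensemble(list(h, h), weights = c(2, 2))
  ft <- frame_features(ens)
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$hbond_score, ft$hbond_score, tolerance = 1e-9)
  expect_equal(back$residue_index, ft$residue_index)
  expect_equal(back$weights, c(2, 2))  # weight values, not counts
  # coordinate and table pathways give identical protection matrices
  pm_a <- protection_matrix(ft)
  pm_b <- protection_matrix(back)
  expect_identical(pm_a$ps, pm_b$ps)
  expect_equal(pm_a$weights, pm_b$weights)
})

test_that("feature-table schema violations are rejected", {
  df <- data.frame(frame = c(1, 1, 2, 2), site = c(2, 3, 2, 3),
                   hbond_score = c(1, 0, 1, 0), bl_bb = 0, bl_sc = 0)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_silent(ftab <- read_feature_table(p))
  expect_equal(dim(ftab$hbond_score), c(2L, 2L))
  utils::write.csv(df[, setdiff(names(df), "hbond_score")], p,
                   row.names = FALSE)
  expect_error(read_feature_table(p), "schema error")
  utils::write.csv(df[-2, ], p, row.names = FALSE)
  expect_error(read_feature_table(p), "completeness")
  df$weight <- c(-1, -1, 1, 1)
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_feature_table(p), "domain error")
})

test_that("site results survive a write/read round trip to 1e-6", {
  m <- hierarchy_model()
  en <- sample_ensemble(m, mode = "enumeration")
  tab <- site_hdx(en$pm, n_boot = 0)
  tab <- site_m_values(tab, en$pm, 0.05, seq(0, 2, by = 0.5))
  path <- tempfile(fileext = ".csv")
  write_site_results(tab, path)
  back <- read_site_results(path)
  expect_equal(nrow(back), nrow(tab))
  for (col in c("dG_HX_kcal_mol", "m_value", "m_closed", "m_open"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-6)
  expect_equal(back$opening_class, tab$opening_class)
  expect_error(write_site_results(tab[0, ], tempfile()), "empty")
})

test_that("JSON run configurations override defaults and catch typos", {
  p <- tempfile(fileext = ".json")
  writeLines('{"temperature_K": 310, "scale_factor_s": 0.08}', p)
  cfg <- read_run_config(p)
  expect_equal(cfg$temperature_K, 310)
  expect_equal(cfg$scale_factor_s, 0.08)
  expect_equal(cfg$burial_cutoff_BL, 5)  # default retained
  writeLines('{"temperatureK": 310}', p)
  expect_error(read_run_config(p), "unknown configuration key")
  expect_error(run_config(temperature_K = -1), "positive")
  expect_error(run_config(denaturant_grid = c(2, 1)), "ascending")
})

test_that("FES grids serialise to JSON with edges and energies", {
  g <- fes_2d(c(0, 0, 1), c(0, 1, 1), bins = 2, temperature_K = 300)
  p <- tempfile(fileext = ".json")
  write_fes_json(g, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$x_edges, g$x_edges, tolerance = 1e-9)
  fe <- back$free_energy
  expect_equal(dim(fe), dim(g$free_energy))
  expect_equal(as.numeric(fe[!is.na(fe)]),
               as.numeric(g$free_energy[!is.na(g$free_energy)]),
               tolerance = 1e-9)
})
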
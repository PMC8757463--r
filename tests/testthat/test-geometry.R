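test_that("inferred amide hydrogen sits 1.01 A from N in the peptide plane", {
  h <- make_helix_fixture(10)
  for (i in c(2, 5, 9)) {
    hp <- infer_amide_hydrogen(h, i)
    expect_equal(sqrt(sum((hp - h$n[i, ])^2)), 1.01, tolerance = 1e-12)
    # coplanar with C(prev), N, CA: zero triple product
    v1 <- h$c[i - 1, ] - h$n[i, ]
    v2 <- h$ca[i, ] - h$n[i, ]
    v3 <- hp - h$n[i, ]
    trip <- sum(v3 * c(v1[2] * v2[3] - v1[3] * v2[2],
                       v1[3] * v2[1] - v1[1] * v2[3],
                       v1[1] * v2[2] - v1[2] * v2[1]))
    expect_lt(abs(trip), 1e-9)
    expect_false(attr(hp, "degenerate"))
  }
  expect_error(infer_amide_hydrogen(h, 1), "no amide")
})

test_that("collinear backbone geometry falls back to a flagged perpendicular H", {
  st <- hx_structure(residue_index = 1:2, residue_name = "ALA",
                     n = rbind(c(0, 0, 0), c(3, 0, 0)),
                     ca = rbind(c(1.4, 0, 0), c(4.4, 0, 0)),
                     c = rbind(c(2, 0, 0), c(5.5, 0, 0)),
                     o = rbind(c(2.2, 1.2, 0), c(5.7, 1.2, 0)))
  hp <- infer_amide_hydrogen(st, 2)  # C(1), N(2), CA(2) all on the x axis
  expect_true(attr(hp, "degenerate"))
  expect_equal(sqrt(sum((hp - st$n[2, ])^2)), 1.01, tolerance = 1e-12)
  expect_lt(abs((hp - st$n[2, ])[1]), 1e-9)  # perpendicular to the axis
})

test_that("proline sites and the N-terminus are excluded from HDX sites", {
  h <- make_helix_fixture(8)
  h$residue_name[4] <- "PRO"
  expect_identical(hdx_sites(h), c(2L, 3L, 5L, 6L, 7L, 8L))
  expect_error(infer_amide_hydrogen(h, 4), "proline")
})

test_that("hbond_score matches its stated logistic switches", {
  # geometry with exact d_HO and theta: N-H along x, O beyond H
  mk <- function(d, theta_deg) {
    th <- theta_deg * pi / 180
    h <- c(0, 0, 0); n <- c(-1.01, 0, 0)
    o <- d * c(cos(pi - th), sin(pi - th), 0)
    cc <- o + c(0, 1.23, 0)
    hbond_score(h, o, n, cc)
  }
  oracle <- function(d, theta)
    1 / (1 + exp((d - 2.5) / 0.25)) * 1 / (1 + exp((120 - theta) / 10))
  for (case in list(c(1.9, 180), c(2.5, 120), c(3.2, 150), c(2.0, 90)))
    expect_equal(mk(case[1], case[2]), oracle(case[1], case[2]),
                 tolerance = 1e-9)
  expect_gt(mk(1.9, 180), 0.9)
  expect_lt(mk(5.0, 180), 0.01)
  expect_lt(mk(5.0, 100), 0.01)
})

test_that("hbond_score is monotone in distance and angle", {
  mk <- function(d, theta_deg) {
    th <- theta_deg * pi / 180
    hbond_score(c(0, 0, 0), d * c(cos(pi - th), sin(pi - th), 0),
                c(-1.01, 0, 0), d * c(cos(pi - th), sin(pi - th), 0) +
                  c(0, 1.23, 0))
  }
  d_ladder <- seq(1.5, 6, by = 0.25)
  expect_true(all(diff(vapply(d_ladder, mk, numeric(1),
                              theta_deg = 170)) < 0))
  a_ladder <- seq(60, 180, by = 5)
  expect_true(all(diff(vapply(a_ladder, function(a) mk(2.0, a),
                              numeric(1))) > 0))
})

test_that("ideal helix fixture exposes exactly the i->i+4 H-bond ladder", {
  h <- make_helix_fixture(15)
  expect_equal(count_hbonds(h), 11L)
  sites <- hdx_sites(h)
  for (i in 5:15) {
    hp <- infer_amide_hydrogen(h, i)
    d_ho <- sqrt(sum((h$o[i - 4, ] - hp)^2))
    expect_lt(d_ho, 2.6)
    sc <- hbond_score(hp, h$o[i - 4, ], h$n[i, ], h$c[i - 4, ])
    expect_gt(sc, 0.5)
  }
  # |i-j| = 3 pairs stay clearly broken
  for (i in sites) for (j in c(i - 3, i + 3)) {
    if (j < 1 || j > 15) next
    hp <- infer_amide_hydrogen(h, i)
    expect_lt(hbond_score(hp, h$o[j, ], h$n[i, ], h$c[j, ]), 0.1)
  }
})

test_that("a score exactly at the threshold counts as an H-bond", {
  sm <- matrix(c(0.5, 0.2, 0.1, 0.49), nrow = 2, byrow = TRUE)
  expect_equal(count_hbonds(sm, hbond_made = 0.5), 1L)
  expect_equal(count_hbonds(matrix(0, 3, 4)), 0L)
})

test_that("burial level matches a brute-force switch sum on the helix", {
  h <- make_helix_fixture(15)
  site <- 8
  bl <- burial_level(h, site)
  hp <- infer_amide_hydrogen(h, site)
  manual <- 0
  for (j in setdiff(1:15, 7:9))
    for (m in list(h$n[j, ], h$ca[j, ], h$c[j, ], h$o[j, ])) {
      d <- sqrt(sum((m - hp)^2))
      manual <- manual + 1 / (1 + exp((d - 6.5) / 0.5))
    }
  expect_equal(bl$bl_bb, manual, tolerance = 1e-9)
  expect_equal(bl$bl_sc, 0)  # fixture has no side chains
  expect_equal(bl$bl_total, bl$bl_bb + 5 * bl$bl_sc)
})

test_that("side-chain centroids carry 5x weight in the burial total", {
  h <- make_helix_fixture(10)
  h$sc <- h$ca + 1.0  # synthetic centroids near the backbone
  bl <- burial_level(h, 5)
  expect_gt(bl$bl_sc, 0)
  expect_equal(bl$bl_total, bl$bl_bb + 5 * bl$bl_sc, tolerance = 1e-12)
})

test_that("an isolated extended tripeptide has near-zero burial", {
  e <- make_extended_fixture(3)
  expect_lt(burial_level(e, 2)$bl_total, 0.5)
})

test_that("radius of gyration matches the closed form", {
  pair <- structure_from_ca(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(pair), 1.0, tolerance = 1e-12)
  h <- make_helix_fixture(12)
  ctr <- colMeans(h$ca)
  brute <- sqrt(mean(rowSums(sweep(h$ca, 2, ctr)^2)))
  expect_equal(radius_of_gyration(h), brute, tolerance = 1e-9)
})

test_that("contact matrix applies the strict 10 A rule and |i-j| >= 2", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(9.9, 0, 0), c(20.0, 0, 0),
              c(30.1, 0, 0))
  cm <- contact_matrix(structure_from_ca(ca))
  expect_equal(cm[1, 3], 1L)   # 9.9 A, in contact
  expect_equal(cm[3, 4], 0L)   # 10.1 A, no contact
  expect_equal(cm[1, 2], 0L)   # |i-j| = 1 excluded even at 3.8 A
  expect_true(all(diag(cm) == 0L))
  set.seed(7)
  cm2 <- contact_matrix(structure_from_ca(matrix(stats::runif(30, 0, 20),
                                                 10, 3)))
  expect_identical(cm2, t(cm2))
  # fully extended chain: contacts only between second neighbours
  e <- make_extended_fixture(10)
  cme <- contact_matrix(e)
  expect_true(all(abs(row(cme) - col(cme))[cme == 1L] == 2))
  expect_gt(sum(cme), 0)
})

test_that("geometry outputs are invariant under rigid isometries", {
  set.seed(11)
  h <- make_helix_fixture(12)
  f0 <- frame_features(hx_ensemble(list(h)))
  for (rep in 1:3) {
    rot <- random_rotation()
    shift <- stats::rnorm(3, 0, 20)
    ht <- transform_structure(h, rot, shift)
    ft <- frame_features(hx_ensemble(list(ht)))
    expect_equal(ft$hbond_score, f0$hbond_score, tolerance = 1e-9)
    expect_equal(ft$bl_bb, f0$bl_bb, tolerance = 1e-9)
    expect_equal(ft$n_hbonds, f0$n_hbonds)
    expect_equal(ft$rg, f0$rg, tolerance = 1e-9)
    expect_identical(contact_matrix(ht), contact_matrix(h))
  }
})

test_that("feature extraction flags H-bonded donors and bounds the score", {
  h <- make_helix_fixture(15)
  ft <- frame_features(hx_ensemble(list(h, h)))
  expect_equal(dim(ft$hbond_score), c(2L, 14L))
  expect_true(all(ft$hbond_score >= 0 & ft$hbond_score <= 1))
  made <- ft$hbond_score[1, ] >= 0.5
  expect_equal(sum(made), 11)  # donors 5..15
  expect_equal(ft$n_hbonds, c(11L, 11L))
})
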
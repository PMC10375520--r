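test_that("rigid superposition recovers exact transforms and never reflects", {
  P <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.2, 0), c(0.3, 0.4, 1.1))
  # identity
  tf <- rigid_align(P, P)
  expect_lt(tf$rmsd, 1e-12)
  expect_lt(max(abs(tf$R - diag(3))), 1e-12)
  # 90 degree rotation about z plus a translation
  Rz <- rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  Q <- sweep(P %*% Rz, 2, c(2, -1, 3), "+")
  tf2 <- rigid_align(P, Q)
  expect_lt(max(abs(tf2$R - Rz)), 1e-8)
  expect_lt(tf2$rmsd, 1e-10)
  expect_lt(max(abs(apply_transform(P, tf2) - Q)), 1e-8)
  # mirror image of a chiral set: best proper rotation keeps a residual
  Qm <- P %*% diag(c(-1, 1, 1))
  tf3 <- rigid_align(P, Qm)
  expect_gt(tf3$rmsd, 0.1)
  expect_equal(det(tf3$R), 1, tolerance = 1e-10)
  # collinear anchors are refused
  L <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(rigid_align(L, L), "collinear")
})

test_that("superposition matches an independent quaternion solver", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    P <- matrix(rnorm(3 * n), n)
    # half the cases: exact rigid copies; half: noisy targets
    Q <- if (rep %% 2 == 0) {
      matrix(rnorm(3 * n), n)
    } else {
      th <- runif(1, 0, pi)
      Rz <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0),
                  c(0, 0, 1))
      sweep(P %*% Rz, 2, rnorm(3), "+") + rnorm(3 * n, sd = 0.05)
    }
    got <- tryCatch(rigid_align(P, Q)$rmsd, error = function(e) NA)
    if (is.na(got)) next  # degenerate draw rejected by the collinearity check
    expect_equal(got, oracle_superpose_rmsd(P, Q), tolerance = 1e-8)
  }
})

test_that("anchor correspondence enumerates local symmetry and keeps the best fit", {
  fx <- toy_fixture_db(8, seed = 31)
  db <- fx$db
  # pick a formic hydroxyl-proton entry and align it onto itself
  hs <- db$entries[db$entries$element == "H", ]
  id <- hs$entry_id[1]
  e <- db$entries[id, ]
  g <- db$graphs[[e$structure_id]]
  desc <- build_descriptor(g, e$site_index, 4)
  coords <- shiftmaps:::molecule_coords(db$structures[[e$structure_id]], g,
                                        e$site_index)
  anchor_sites <- c(e$site_index, shiftmaps:::graph_adjacency(g)[[e$site_index]][1])
  # extend anchors to 4 atoms within two bonds
  nb <- shiftmaps:::graph_adjacency(g)[[anchor_sites[2]]]
  anchor_sites <- unique(c(anchor_sites, nb))[1:4]
  ac <- anchor_correspondence(desc, anchor_sites,
                              coords[anchor_sites, , drop = FALSE],
                              db, id, 4)
  expect_lt(ac$rmsd, 1e-8)
  expect_equal(ac$db_anchor_sites, anchor_sites)
  # anchors outside the descriptor depth are a configuration error
  d1 <- build_descriptor(g, e$site_index, 1)
  expect_error(anchor_correspondence(d1, anchor_sites,
                                     coords[anchor_sites, , drop = FALSE],
                                     db, id, 1),
               "outside descriptor depth")
})

test_that("methyl-rotor automorphisms are resolved by minimum RMSD", {
  # methane-like: C center with 3 equivalent H plus one distinct N cap;
  # the three H are interchangeable, giving several witness isomorphisms
  elements <- c("C", "H", "H", "H", "N")
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))
  g <- bond_graph(elements, edges)
  d <- build_descriptor(g, 1, 1)
  mm <- descriptors_match(d, d, all_mappings = TRUE)
  expect_true(mm$match)
  expect_equal(length(mm$mappings), 6L)  # 3! permutations of the H atoms
})

test_that("the default grid has 31 points over 12 A giving 0.4 A spacing", {
  g <- grid_spec()
  expect_equal(g$points, 31L)
  expect_equal(g$side, 12)
  expect_equal(g$spacing, 0.4)
  expect_equal(g$ax[2] - g$ax[1], 0.4)
  expect_error(grid_spec(points = 1), "points")
})

test_that("density accumulation is exactly normalized and matches closed forms", {
  g <- grid_spec(31, 12, center = c(0, 0, 0))
  # an H at the grid center in every environment -> value exactly 1 there
  envs <- lapply(1:20, function(i) point_env(c(0, 0, 0), "H"))
  m <- accumulate_density(envs, g, "H")
  ctr <- 16L
  expect_equal(m$values[ctr, ctr, ctr], 1, tolerance = 1e-6)
  # adjacent grid point: unit Gaussian at one spacing, exp(-0.4^2/(2*0.25))
  single <- accumulate_density(list(point_env(c(0, 0, 0), "H")), g, "H")
  expect_equal(single$values[ctr + 1L, ctr, ctr], exp(-0.32),
               tolerance = 1e-9)
  # an element absent from every environment gives an all-zero map
  zero <- accumulate_density(envs, g, "Cl")
  expect_equal(max(abs(zero$values)), 0)
  # closed form at an arbitrary off-grid atom position
  pos <- c(0.13, -0.21, 0.07)
  m2 <- accumulate_density(list(point_env(pos, "H")), g, "H")
  r2 <- sum((c(g$ax[17], g$ay[15], g$az[16]) - pos)^2)
  expect_equal(m2$values[17, 15, 16], exp(-r2 / (2 * 0.25)),
               tolerance = 1e-12)
})

test_that("density is permutation invariant and respects the mass bound", {
  set.seed(41)
  g <- grid_spec(31, 12, center = c(0, 0, 0))
  envs <- lapply(1:15, function(i) {
    n <- sample(3:6, 1)
    point_env(matrix(rnorm(3 * n, sd = 2), n),
              sample(c("H", "O"), n, replace = TRUE))
  })
  m1 <- accumulate_density(envs, g, "H")
  m2 <- accumulate_density(rev(envs), g, "H")
  expect_equal(m1$values, m2$values)
  # integral bound: mean H count per env times the Gaussian volume
  mean_h <- mean(vapply(envs, function(e) sum(e$elements == "H"),
                        numeric(1)))
  integral <- sum(m1$values) * g$spacing^3
  expect_lte(integral, mean_h * (2 * pi * 0.25)^1.5 * 1.05)
})

test_that("difference maps subtract, threshold and reverse correctly", {
  g <- grid_spec(11, 4, center = c(0, 0, 0))
  base <- array(0.5, rep(11, 3))
  sim <- density_map(base, g, "O", 10L, "SIM")
  iim <- density_map(base, g, "O", 10L, "IIM")
  expect_equal(max(abs(difference_map(sim, iim)$values)), 0)
  # sub-threshold differences are zeroed exactly; larger ones retained
  v <- base; v[2, 3, 4] <- 0.5 + 0.005; v[5, 6, 7] <- 0.5 + 0.15
  sim2 <- density_map(v, g, "O", 10L, "SIM")
  d <- difference_map(sim2, iim)
  expect_identical(d$values[2, 3, 4], 0)
  expect_equal(d$values[5, 6, 7], 0.15)
  # reverse flag flips the sign convention
  drev <- difference_map(sim2, iim, reverse = TRUE)
  expect_equal(drev$values[5, 6, 7], -0.15)
  # mismatched grids are a shape error
  g2 <- grid_spec(11, 4, center = c(1, 0, 0))
  sim3 <- density_map(base, g2, "O", 10L, "SIM")
  expect_error(difference_map(sim3, iim), "grid mismatch")
})

test_that("maps are invariant under a global rigid transform of the inputs", {
  fx <- toy_fixture_db(10, seed = 51)
  db <- fx$db
  cs <- make_candidate_set(n_decoys = 0, include_truth = FALSE, seed = 52)
  asn <- formic_assignments()
  fit1 <- shift_maps(db, cs$molecule, asn, formic_anchors(), n_select = 12,
                     min_matches = 5, seed = 420)
  # rigidly translating every database structure (fractional shift) must
  # leave every aligned map unchanged
  shifted <- lapply(db$structures, function(st) {
    st$frac <- (st$frac + rep(c(0.31, 0.57, 0.11), each = nrow(st$frac))) %% 1
    st
  })
  db2 <- build_database(shifted, fx$shifts)
  fit2 <- shift_maps(db2, cs$molecule, asn, formic_anchors(), n_select = 12,
                     min_matches = 5, seed = 420)
  for (lab in names(fit1$sites)) {
    for (el in names(fit1$sites[[lab]]$sim_maps)) {
      expect_lt(max(abs(fit1$sites[[lab]]$sim_maps[[el]]$values -
                          fit2$sites[[lab]]$sim_maps[[el]]$values)), 1e-6)
      expect_lt(max(abs(fit1$sites[[lab]]$iim_maps[[el]]$values -
                          fit2$sites[[lab]]$iim_maps[[el]]$values)), 1e-6)
    }
  }
  # rotating every extracted environment before alignment likewise cancels
  s <- fit1$sites$H2
  ids <- s$sim_ids[1:5]
  th <- 0.83
  Rz <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  tf_global <- list(R = Rz, t = c(3.2, -1.1, 0.7))
  envs_plain <- lapply(ids, function(id)
    aligned_environment(s$descriptor, s$anchor_sites, s$anchor_coords,
                        db, id, s$w))
  # transform raw environments and re-fit the anchors on transformed coords
  envs_moved <- lapply(ids, function(id) {
    e <- db$entries[id, ]
    env <- expand_to_sphere(db$structures[[e$structure_id]], e$site_index, 7)
    env <- shiftmaps:::transform_env(env, tf_global)
    ac <- anchor_correspondence(s$descriptor, s$anchor_sites,
                                s$anchor_coords, db, id, s$w)
    P <- apply_transform(ac$db_anchor_xyz, tf_global)
    tf <- rigid_align(P, s$anchor_coords)
    shiftmaps:::transform_env(env, tf)
  })
  m_plain <- accumulate_density(envs_plain, s$grid, "O")
  m_moved <- accumulate_density(envs_moved, s$grid, "O")
  expect_lt(max(abs(m_plain$values - m_moved$values)), 1e-6)
})
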
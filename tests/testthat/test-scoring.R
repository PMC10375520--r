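make_map <- function(values, g, el, kind) density_map(values, g, el, 1L, kind)

test_that("site scores are signed voxelwise overlaps with the difference map", {
  g <- grid_spec(11, 4, center = c(0, 0, 0))
  zero <- array(0, rep(11, 3))
  cand <- zero; cand[4, 5, 6] <- 1
  cmap <- list(O = make_map(cand, g, "O", "candidate"))
  # SIM = IIM -> exactly zero
  base <- array(0.3, rep(11, 3))
  expect_identical(site_score(cmap,
                              list(O = make_map(base, g, "O", "SIM")),
                              list(O = make_map(base, g, "O", "IIM"))), 0)
  # +0.2 difference under the candidate voxel -> 0.2; sign flips with it
  up <- base; up[4, 5, 6] <- 0.5
  expect_equal(site_score(cmap, list(O = make_map(up, g, "O", "SIM")),
                          list(O = make_map(base, g, "O", "IIM"))), 0.2)
  expect_equal(site_score(cmap, list(O = make_map(base, g, "O", "SIM")),
                          list(O = make_map(up, g, "O", "IIM"))), -0.2)
  # channels sum: duplicate the situation on H
  cmap2 <- c(cmap, list(H = make_map(cand, g, "H", "candidate")))
  s2 <- site_score(cmap2,
                   list(O = make_map(up, g, "O", "SIM"),
                        H = make_map(up, g, "H", "SIM")),
                   list(O = make_map(base, g, "O", "IIM"),
                        H = make_map(base, g, "H", "IIM")))
  expect_equal(s2, 0.4)
})

test_that("site score is linear in candidate and difference maps", {
  set.seed(90)
  g <- grid_spec(9, 4, center = c(0, 0, 0))
  arr <- function() array(runif(9^3), rep(9, 3))
  sim <- list(O = make_map(arr(), g, "O", "SIM"))
  iim <- list(O = make_map(arr(), g, "O", "IIM"))
  c1 <- list(O = make_map(arr(), g, "O", "candidate"))
  c2 <- list(O = make_map(arr(), g, "O", "candidate"))
  s1 <- site_score(c1, sim, iim)
  s2 <- site_score(c2, sim, iim)
  csum <- list(O = make_map(c1$O$values + 2 * c2$O$values, g, "O",
                            "candidate"))
  expect_equal(site_score(csum, sim, iim), s1 + 2 * s2, tolerance = 1e-10)
  # linear in the (already thresholded) difference map as well
  d <- difference_maps(sim, iim)
  d3 <- list(O = make_map(3 * d$O$values, g, "O", "difference"))
  expect_equal(site_score(c1, diff_maps = d3),
               3 * site_score(c1, diff_maps = d), tolerance = 1e-10)
})

test_that("global scores average unambiguous sites and report exclusions", {
  gs <- global_score(c(a = 0.1, b = 0.3))
  expect_equal(gs$global, 0.2)
  # an ambiguous site is excluded no matter how extreme its score
  gs2 <- global_score(c(a = 0.1, b = 0.3, c = 99),
                      ambiguous = c(FALSE, FALSE, TRUE))
  expect_equal(gs2$global, 0.2)
  expect_equal(gs2$excluded$label, "c")
  expect_equal(gs2$excluded$reason, "ambiguous")
  expect_equal(global_score(c(x = 0.7))$global, 0.7)
  expect_error(global_score(c(a = 1), ambiguous = TRUE), "empty-score")
})

test_that("score normalization centers the candidate set", {
  expect_equal(normalize_scores(c(0.4, 0.0, -0.1)), c(0.3, -0.1, -0.2))
  expect_equal(normalize_scores(rep(0.25, 4)), rep(0, 4))
  expect_equal(normalize_scores(c(0.3, -0.3)), c(0.3, -0.3))
  expect_lt(abs(sum(normalize_scores(runif(7)))), 1e-10)
  expect_warning(out <- normalize_scores(c(a = 0.5)), "single candidate")
  expect_equal(out, c(a = 0.5))
})

test_that("ambiguity flags follow descriptor equivalence with shift conflicts", {
  # propane-like CH2: central carbon protons share a descriptor
  g <- ethanol_graph()
  # the two CH2 protons (nodes 7, 8) with different shifts -> both flagged
  asn <- assignment_table(label = c("H7", "H8"), nucleus = c("H", "H"),
                          shift_ppm = c(3.6, 3.9))
  expect_equal(flag_ambiguous_sites(g, asn, w = 3), c(TRUE, TRUE))
  # one shared entry for the pair -> a single unambiguous map
  asn2 <- assignment_table(label = "H7", nucleus = "H", shift_ppm = 3.7)
  expect_equal(flag_ambiguous_sites(g, asn2, w = 3), FALSE)
  # chemically unique site -> never flagged
  asn3 <- assignment_table(label = c("H9", "H7"), nucleus = c("H", "H"),
                           shift_ppm = c(5.2, 3.7))
  expect_equal(flag_ambiguous_sites(g, asn3, w = 3), c(FALSE, FALSE))
})

test_that("a candidate identical to the reference renders its own surroundings", {
  cs <- make_candidate_set(n_decoys = 0, seed = 61)
  cand <- cs$candidates$cand_dimer
  g <- perceive_bonds(cand)
  h2 <- match("H2", g$labels)
  desc <- build_descriptor(g, h2, 6)
  coords <- shiftmaps:::molecule_coords(cand, g, h2)
  anchor_sites <- match(c("H2", "O2", "C1", "O1"), g$labels)
  grid <- grid_spec(31, 12, center = coords[h2, ])
  maps <- candidate_site_map(cand, desc, anchor_sites,
                             coords[anchor_sites, , drop = FALSE], grid)
  # aligning the candidate onto its own conformation is the identity, so
  # every own-atom position carries density ~1 (n_envs = 1 normalization)
  env <- expand_to_sphere(cand, h2, 7)
  for (k in seq_along(env$elements)[1:5]) {
    el <- env$elements[k]
    pos <- env$xyz[k, ]
    gi <- vapply(1:3, function(ax)
      which.min(abs(switch(ax, grid$ax, grid$ay, grid$az) - pos[ax])),
      integer(1))
    near2 <- sum((c(grid$ax[gi[1]], grid$ay[gi[2]], grid$az[gi[3]]) -
                    pos)^2)
    expect_gte(maps[[el]]$values[gi[1], gi[2], gi[3]],
               exp(-near2 / (2 * 0.25)) - 1e-6)
  }
  # a candidate lacking any matching site is an assignment error
  meth <- shiftmaps:::build_motif("isolated", "m", c(10, 12),
                                  species = "methanol")
  expect_error(candidate_site_map(meth, desc, anchor_sites,
                                  coords[anchor_sites, , drop = FALSE],
                                  grid),
               "assignment error")
})

test_that("candidates scored against equal SIM and IIM all normalize to zero", {
  fx <- toy_fixture_db(8, seed = 62)
  cs <- make_candidate_set(n_decoys = 2, seed = 63)
  fit <- shift_maps(fx$db, cs$molecule, formic_assignments(),
                    formic_anchors(), n_select = 8, min_matches = 3,
                    seed = 64)
  # force SIM = IIM: zero difference everywhere
  for (lab in names(fit$sites)) {
    for (el in names(fit$sites[[lab]]$diff_maps)) {
      fit$sites[[lab]]$diff_maps[[el]]$values[] <- 0
    }
  }
  rep <- predict(fit, cs$candidates)
  expect_equal(rep$global_score, rep(0, nrow(rep)))
  expect_equal(rep$normalized_score, rep(0, nrow(rep)))
})

test_that("identical candidates tie with stable id order", {
  fx <- toy_fixture_db(8, seed = 65)
  cs <- make_candidate_set(n_decoys = 0, seed = 66)
  dupes <- list(dup_a = cs$candidates$cand_dimer,
                dup_b = cs$candidates$cand_dimer)
  dupes$dup_a$structure_id <- "dup_a"
  dupes$dup_b$structure_id <- "dup_b"
  fit <- shift_maps(fx$db, cs$molecule, formic_assignments(),
                    formic_anchors(), n_select = 8, min_matches = 3,
                    seed = 67)
  rep <- predict(fit, dupes)
  expect_equal(rep$global_score[1], rep$global_score[2])
  expect_equal(rep$candidate_id, c("dup_a", "dup_b"))
  expect_equal(rep$rank, 1:2)
})

test_that("environments selected by shift outscore random draws against their SIM", {
  # paired comparison: score the SIM's own top environments vs random ones
  fx <- toy_fixture_db(16, seed = 68)
  db <- fx$db
  cs <- make_candidate_set(n_decoys = 0, include_truth = FALSE, seed = 69)
  asn <- assignment_table("H2", "H", 10)
  fit <- shift_maps(db, cs$molecule, asn, formic_anchors(), n_select = 10,
                    min_matches = 3, seed = 70)
  s <- fit$sites$H2
  pool <- db$entries[db$entries$entry_id %in%
                       query_database(db, s$descriptor), ]
  score_env <- function(id) {
    env <- aligned_environment(s$descriptor, s$anchor_sites,
                               s$anchor_coords, db, id, s$w)
    cm <- density_maps(list(env), s$grid, kind = "candidate")
    site_score(cm, diff_maps = s$diff_maps)
  }
  scores <- setNames(vapply(pool$entry_id, score_env, numeric(1)),
                     pool$entry_id)
  wins <- 0L
  for (rep in 1:100) {
    sim_ids <- select_by_shift_1d(pool,
                                  selection_spec("shift_1d", n = 5,
                                                 targets = 10, sigma = 0.5,
                                                 seed = 7000 + rep))
    rnd_ids <- select_random(pool$entry_id,
                             selection_spec("random", n = 5,
                                            seed = 8000 + rep))
    if (mean(scores[as.character(sim_ids)]) >
        mean(scores[as.character(rnd_ids)])) wins <- wins + 1L
  }
  # sign test at alpha = 0.01 against p = 0.5
  expect_gt(wins, qbinom(0.99, 100, 0.5))
})
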
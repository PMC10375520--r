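test_that("database construction indexes every shift record and validates input", {
  fx <- toy_fixture_db(6, seed = 21)
  db <- fx$db
  expect_equal(nrow(db$entries), nrow(fx$shifts))
  expect_false(any(is.na(db$keys)))
  # every entry's nucleus equals its site element
  for (r in seq_len(nrow(db$entries))) {
    st <- db$structures[[db$entries$structure_id[r]]]
    expect_equal(st$elements[db$entries$site_index[r]],
                 db$entries$element[r])
  }
  # rebuilding the index from the key matrix reproduces it
  rebuilt <- lapply(seq_len(db$w_max), function(w)
    split(db$entries$entry_id, db$keys[, w]))
  expect_equal(rebuilt, db$index)
  # dangling structure id
  bad <- fx$shifts
  bad$structure_id[1] <- "nonexistent"
  expect_error(build_database(fx$toy$structures, bad), "unknown structure")
  # duplicate (structure, site)
  dup <- rbind(fx$shifts, fx$shifts[1, ])
  expect_error(build_database(fx$toy$structures, dup), "duplicate")
  # nucleus mismatching the site element
  swap <- fx$shifts
  swap$nucleus[1] <- if (swap$nucleus[1] == "H") "C" else "H"
  expect_error(build_database(fx$toy$structures, swap), "does not match")
  # empty shift table -> empty database, queries return nothing
  empty <- build_database(fx$toy$structures, fx$shifts[0, ])
  expect_equal(nrow(empty$entries), 0L)
  g <- db$graphs[[1]]
  expect_length(query_database(empty, build_descriptor(g, 1, 3)), 0L)
})

test_that("queries equal an exhaustive isomorphism scan", {
  fx <- toy_fixture_db(10, seed = 22)
  db <- fx$db
  g <- db$graphs[[db$entries$structure_id[1]]]
  for (w in c(2L, 4L)) {
    for (site in unique(db$entries$site_index[
      db$entries$structure_id == db$entries$structure_id[1]])[1:3]) {
      q <- build_descriptor(g, site, w)
      got <- query_database(db, q)
      # exhaustive: match q against every entry descriptor directly
      want <- db$entries$entry_id[vapply(db$entries$entry_id, function(id) {
        e <- db$entries[id, ]
        d <- build_descriptor(db$graphs[[e$structure_id]], e$site_index, w)
        oracle_descriptor_match(q, d)
      }, logical(1))]
      expect_equal(got, sort(want))
    }
  }
})

test_that("database round-trips through its serialized container", {
  fx <- toy_fixture_db(4, seed = 23)
  path <- tempfile(fileext = ".rds")
  save_database(fx$db, path)
  back <- load_database(path)
  expect_equal(back$entries, fx$db$entries)
  expect_equal(back$keys, fx$db$keys)
  saveRDS(list(not = "a db"), path)
  expect_error(load_database(path), "version-1")
})

test_that("random selection is uniform, distinct and reproducible", {
  ids <- 1:100
  spec <- selection_spec("random", n = 10, seed = 99)
  s1 <- select_random(ids, spec)
  s2 <- select_random(ids, spec)
  expect_equal(sort(s1), sort(s2))
  expect_equal(length(unique(s1)), 10L)
  # n = pool size returns the whole pool; larger n errors
  expect_equal(sort(select_random(1:10, selection_spec("random", n = 10,
                                                       seed = 1))), 1:10)
  expect_error(select_random(1:9, selection_spec("random", n = 10)),
               "insufficient matches")
  # aggregate counts over many seeded draws pass a chi-square uniformity test
  counts <- integer(100)
  for (rep in 1:500) {
    sel <- select_random(ids, selection_spec("random", n = 10,
                                             seed = 1000 + rep))
    counts[sel] <- counts[sel] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("1D shift-targeted selection tracks the target distribution", {
  # two well-separated entries: the near one wins essentially always
  entries <- data.frame(entry_id = c(1L, 2L), shift = c(1.0, 9.0))
  wins <- 0L
  for (rep in 1:200) {
    sel <- select_by_shift_1d(entries,
                              selection_spec("shift_1d", n = 1, targets = 1.2,
                                             sigma = 0.5, seed = rep))
    if (sel == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 195L)
  # all-equal shifts degenerate to the deterministic tie order
  ties <- data.frame(entry_id = 5:1, shift = rep(5, 5))
  sel <- select_by_shift_1d(ties, selection_spec("shift_1d", n = 3,
                                                 targets = 5, sigma = 1,
                                                 seed = 4))
  expect_equal(sel, 1:3)  # ascending entry id
  # sigma -> 0 limit: the n entries nearest the target, in distance order
  set.seed(61)
  pool <- data.frame(entry_id = 1:50, shift = runif(50, 0, 20))
  sel0 <- select_by_shift_1d(pool, selection_spec("shift_1d", n = 8,
                                                  targets = 10,
                                                  sigma = 1e-9, seed = 5))
  oracle <- pool$entry_id[order(abs(pool$shift - 10), pool$entry_id)][1:8]
  expect_equal(sel0, oracle)
})

test_that("selected-shift statistics reproduce the sampling Gaussian", {
  # dense pool: nearest-available selection barely perturbs the draws
  set.seed(71)
  pool <- data.frame(entry_id = seq_len(20000),
                     shift = runif(20000, 0, 20))
  target <- 10; sigma <- 0.5; n <- 1000
  sel <- select_by_shift_1d(pool, selection_spec("shift_1d", n = n,
                                                 targets = target,
                                                 sigma = sigma, seed = 72))
  got <- pool$shift[match(sel, pool$entry_id)]
  expect_lt(abs(mean(got) - target), 3 * sigma / sqrt(n))
  expect_lt(abs(sd(got) - sigma) / sigma, 0.20)
  # no duplicates ever
  expect_equal(anyDuplicated(sel), 0L)
})

test_that("the 2D shift distance is the sigma-normalized Euclidean form", {
  expect_equal(shift_distance_2d(120, 7.0, c(120, 7.0), 5, 0.5), 0)
  expect_equal(shift_distance_2d(125, 7.0, c(120, 7.0), 5, 0.5), 1.0)
  expect_equal(shift_distance_2d(125, 7.5, c(120, 7.0), 5, 0.5), sqrt(2))
  # symmetric in the sign of the deviation
  expect_equal(shift_distance_2d(115, 6.5, c(120, 7.0), 5, 0.5), sqrt(2))
  expect_error(shift_distance_2d(1, 1, c(1, 1), 0, 0.5), "widths")
})

test_that("2D shift-targeted selection picks the nearest correlated pair", {
  one <- data.frame(entry_id = 1L, shift_c = 120, shift_h = 7)
  expect_equal(select_by_shift_2d(one,
                                  selection_spec("shift_2d", n = 1,
                                                 targets = c(118, 6.8),
                                                 seed = 1)), 1L)
  two <- data.frame(entry_id = 1:2, shift_c = c(120, 20),
                    shift_h = c(7, 1))
  wins <- 0L
  for (rep in 1:200) {
    sel <- select_by_shift_2d(two, selection_spec("shift_2d", n = 1,
                                                  targets = c(118, 6.8),
                                                  seed = rep))
    if (sel == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 195L)
  # sigma -> 0 limit ranks by the 2D distance
  set.seed(81)
  pool <- data.frame(entry_id = 1:40, shift_c = runif(40, 0, 200),
                     shift_h = runif(40, 0, 12))
  sel0 <- select_by_shift_2d(pool,
                             selection_spec("shift_2d", n = 6,
                                            targets = c(120, 7),
                                            sigma = c(1e-9, 1e-10),
                                            seed = 9))
  d <- mapply(function(c, h) shift_distance_2d(c, h, c(120, 7), 5, 0.5),
              pool$shift_c, pool$shift_h)
  oracle <- pool$entry_id[order(d, pool$entry_id)][1:6]
  expect_equal(sel0, oracle)
})
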
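test_that("band slicing yields one conduit per covered band", {
  # one full-height band on a rectangular cell: exactly one conduit
  map <- make_strip_map(c("A", "B", "C"))
  st <- compute_activities(assign_expression(
    map, strip_params(c(A = 0.2, B = 0.5, C = 0.8))))
  b <- relax_bonds(initialise_bonds(map, st))
  c1 <- build_conduits(map, b, band_width = map$cell_size)
  expect_equal(sum(c1$cell == 2), 1)
  # edge cells have an uncovered side: no conduit at all
  expect_equal(sum(c1$cell == 1), 0)
  expect_equal(sum(c1$cell == 3), 0)
  # 5 um bands: six conduits across a 30 um cell
  c6 <- build_conduits(map, b, band_width = 5)
  expect_equal(sum(c6$cell == 2), 6)
  expect_error(build_conduits(map, b, band_width = 0), "band_width")
})

test_that("atypical cells get conduits abutting different posterior rows", {
  run <- cached_run("atypical_row4")
  at <- run$map$cells$id[run$map$cells$is_atypical]
  ca <- run$conduits[run$conduits$cell == at, ]
  expect_setequal(unique(ca$post_labels), c("T2", "4"))
  expect_equal(unique(ca$ant_labels), "3")
  expect_gte(nrow(ca), 2)
})

test_that("symmetric neighbours give an exactly zero score", {
  map <- make_strip_map(c("A", "B", "A"))
  st <- compute_activities(assign_expression(
    map, strip_params(c(A = 0.6, B = 0.4))))
  b <- relax_bonds(initialise_bonds(map, st), tol = 1e-13)
  cond <- score_conduits(build_conduits(map, b), b)
  expect_lt(abs(cond$score[cond$cell == 2][1]), 1e-10)
  expect_equal(unique(cond$call[cond$cell == 2]), "unpolarized")
})

test_that("scores are antisymmetric under mirroring", {
  map <- build_segment_map(n_columns = 2, trailing_p = TRUE)
  st <- compute_activities(assign_expression(map))
  b <- relax_bonds(initialise_bonds(map, st))
  cond <- score_conduits(build_conduits(map, b), b)
  mm <- mirror_map(map)
  stm <- compute_activities(assign_expression(mm))
  bm <- relax_bonds(initialise_bonds(mm, stm))
  condm <- score_conduits(build_conduits(mm, bm), bm)
  for (id in map$cells$id[!map$cells$is_tendon]) {
    s <- cond[cond$cell == id, ]
    sm <- condm[condm$cell == id, ]
    expect_equal(nrow(s), nrow(sm))
    if (nrow(s) == 0) next
    expect_lt(max(abs(s$score + sm$score)), 1e-8)
    flip <- c(anterior = "posterior", posterior = "anterior",
              unpolarized = "unpolarized")
    expect_identical(unname(flip[s$call]), sm$call)
  }
})

test_that("conduit score rises monotonically with posterior-neighbour Ds", {
  scores <- vapply(seq(0.1, 1.5, by = 0.2), function(dsC) {
    map <- make_strip_map(c("A", "B", "C"))
    st <- compute_activities(assign_expression(
      map, strip_params(c(A = 0.5, B = 0.5, C = dsC))))
    b <- relax_bonds(initialise_bonds(map, st), tol = 1e-12)
    cond <- score_conduits(build_conduits(map, b), b)
    cond$score[cond$cell == 2][1]
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # sign flips around equality with the anterior neighbour
  expect_lt(scores[1], 0)
  expect_gt(scores[length(scores)], 0)
})

test_that("conduits are local: bands reference only overlapping segments", {
  run <- cached_run("atypical_row4")
  seg <- run$bonds$seg
  for (i in seq_len(nrow(run$conduits))) {
    for (side in c("ant_refs", "post_refs")) {
      refs <- run$conduits[[side]][[i]]
      lo <- seg$lo[refs$idx]; hi <- seg$hi[refs$idx]
      expect_true(all(hi > run$conduits$y0[i] - 1e-9 &
                      lo < run$conduits$y1[i] + 1e-9))
    }
  }
})

test_that("cell classification follows the conduit calls", {
  calls <- function(v) data.frame(
    conduit = seq_along(v), cell = 1L, band = seq_along(v),
    y0 = 0, y1 = 1, ant_labels = "x", post_labels = "y", score = 0,
    theta = 0, call = v, stringsAsFactors = FALSE)
  map1 <- make_strip_map("3")
  expect_equal(classify_cells(calls(c("anterior", "posterior")), map1)$class,
               "multipolar")
  expect_equal(classify_cells(calls(c("anterior", "unpolarized")), map1)$class,
               "unipolar_anterior")
  expect_equal(classify_cells(calls(rep("unpolarized", 3)), map1)$class,
               "unpolarized")
  empty <- calls("anterior")[0, ]
  cl <- classify_cells(empty, map1)
  expect_equal(cl$class, "unpolarized")
  expect_true(cl$no_conduits)
})

test_that("denticle placement follows calls and is reproducible", {
  run <- cached_run("wildtype")
  set.seed(11)
  dent <- place_denticles(run$map, run$conduits, count = 3)
  # polarized conduits: membrane-adjacent, orientation inherited
  pol <- run$conduits$conduit[run$conduits$call != "unpolarized"]
  dp <- dent[dent$conduit %in% pol, ]
  expect_true(all(dp$placement == "membrane"))
  byc <- tapply(dp$orientation, dp$conduit, function(x) length(unique(x)))
  expect_true(all(byc == 1))
  expect_equal(nrow(dp), 3 * length(pol))
  # tendon cells never carry denticles
  tend <- run$map$cells$id[run$map$cells$is_tendon]
  expect_false(any(dent$cell %in% tend))
  # P-compartment cells carry none either
  pcells <- run$map$cells$id[run$map$cells$row_label == "P"]
  expect_false(any(dent$cell %in% pcells))
  # same seed, same denticles
  set.seed(11)
  expect_identical(place_denticles(run$map, run$conduits, count = 3), dent)
})

test_that("bond-free tissue draws orientations uniformly", {
  cfg <- scenario_config("ds_ft_null", seed = 5, denticles_per_conduit = 4L)
  run <- run_scenario(cfg)
  dent <- run$denticles
  expect_true(all(dent$placement == "central"))
  expect_gte(nrow(dent), 1000)
  k <- sum(dent$orientation == "anterior"); n <- nrow(dent)
  # within 5 binomial sd of one half
  expect_lt(abs(k - n / 2), 5 * sqrt(n * 0.25))
})
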
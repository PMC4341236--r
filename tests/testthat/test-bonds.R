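test_that("initial allocation spreads pools over the boundary", {
  # single square cell: each of the four equal edges carries 25% of the pool
  map <- make_strip_map("A")
  st <- compute_activities(assign_expression(map, strip_params(c(A = 1))))
  b <- initialise_bonds(map, st)
  seg <- b$seg
  edge <- ifelse(seg$axis == "ap", paste0("x", seg$pos), paste0("y", seg$pos))
  share <- tapply(seg$free_ds_a * seg$length, edge, sum) / b$pools$pool_ds[1]
  expect_equal(as.vector(share), rep(0.25, 4), tolerance = 1e-12)
})

test_that("null genotypes carry no protein and form no bonds", {
  map <- make_strip_map(c("A", "B"))
  map$cells$ds_null <- TRUE
  st <- apply_genotype(compute_activities(
    assign_expression(map, strip_params(c(A = 1, B = 1)))), map)
  b <- relax_bonds(initialise_bonds(map, st))
  expect_true(all(b$seg$free_ds_a == 0 & b$seg$free_ds_b == 0))
  expect_true(all(b$seg$bond_ab == 0 & b$seg$bond_ba == 0))

  map$cells$ft_null <- TRUE
  st2 <- apply_genotype(compute_activities(
    assign_expression(map, strip_params(c(A = 1, B = 1)))), map)
  b2 <- relax_bonds(initialise_bonds(map, st2))
  expect_true(all(b2$seg$bond_ab == 0 & b2$seg$bond_ba == 0))
  expect_equal(bond_conservation(b2), 0)
})

test_that("a Ds-only cell facing an Ft-only cell forms one bridge species", {
  map <- make_strip_map(c("A", "B"))
  st <- compute_activities(assign_expression(
    map, strip_params(c(A = 1, B = 0), ft = c(A = 0, B = 1))))
  b <- relax_bonds(initialise_bonds(map, st))
  int <- !is.na(b$seg$cell_b)
  expect_true(all(b$seg$bond_ab[int] > 0))  # Ds from A, Ft from B
  expect_true(all(b$seg$bond_ba == 0))      # no reciprocal species possible
})

test_that("conservation holds at every relaxation step", {
  map <- build_segment_map(n_columns = 2, trailing_p = TRUE)
  st <- compute_activities(assign_expression(map))
  b <- relax_bonds(initialise_bonds(map, st), record_conservation = TRUE)
  expect_true(b$converged)
  expect_true(all(b$conservation_trace <= 1e-8))
  expect_lt(bond_conservation(b), 1e-8)
})

test_that("the fixed point matches the brute-force oracle on small systems", {
  cases <- list(
    list(labels = c("A", "B"), ds = c(A = 0.2, B = 0.9)),
    list(labels = c("A", "B", "C"), ds = c(A = 0.1, B = 0.5, C = 0.9)),
    list(labels = c("A", "B", "C", "D"), ds = c(A = 0.7, B = 0.2, C = 0.9, D = 0.4))
  )
  for (cs in cases) {
    map <- make_strip_map(cs$labels)
    st <- compute_activities(assign_expression(map, strip_params(cs$ds)))
    b <- relax_bonds(initialise_bonds(map, st), tol = 1e-12)
    o <- oracle_relax(map, st, tol = 1e-12)
    expect_lt(max(abs(b$seg$bond_ab - o$bond_ab)), 1e-8)
    expect_lt(max(abs(b$seg$bond_ba - o$bond_ba)), 1e-8)
  }
})

test_that("a low-mid-high Ds chain biases the middle cell's own-Ft bonds", {
  # brute-force oracle fixes the expected sign of the asymmetry
  map <- make_strip_map(c("L", "M", "H"))
  st <- compute_activities(assign_expression(
    map, strip_params(c(L = 0.1, M = 0.5, H = 0.9))))
  o <- oracle_relax(map, st, tol = 1e-12)
  seg <- map$segments
  lo_side <- which(!is.na(seg$cell_b) & seg$cell_a == 1 & seg$cell_b == 2)
  hi_side <- which(!is.na(seg$cell_b) & seg$cell_a == 2 & seg$cell_b == 3)
  # own-Ft of M: Ft^M sits in bond_ab on the L|M interface (M is side b)
  # and in bond_ba on the M|H interface (M is side a)
  expect_gt(mean(o$bond_ba[hi_side]), mean(o$bond_ab[lo_side]))
  # and the implementation agrees
  b <- relax_bonds(initialise_bonds(map, st), tol = 1e-12)
  expect_gt(mean(b$seg$bond_ba[hi_side]), mean(b$seg$bond_ab[lo_side]))
})

test_that("uniform activities give a symmetric fixed point", {
  # 11-row lattice (trailing P) puts row 3 exactly at the centre
  map <- build_segment_map(n_columns = 3, n_segments = 1, trailing_p = TRUE)
  p <- default_expression_params()
  p$ds_expr <- 0.5; p$ft_expr <- 1; p$fj_expr <- 0
  st <- compute_activities(assign_expression(map, p))
  b <- relax_bonds(initialise_bonds(map, st))
  # centre cell: anterior and posterior own-Ft totals agree
  id <- map$cells$id[map$cells$row_label == "3" & map$cells$col == 2]
  bs <- bond_summary(b, id)
  ant <- bs$faces == "anterior"; post <- bs$faces == "posterior"
  expect_lt(abs(sum(bs$own_ft[ant] * bs$length[ant]) -
                sum(bs$own_ft[post] * bs$length[post])), 1e-8)
})

test_that("bond summaries reproduce the bridge-majority colouring", {
  run <- cached_run("wildtype")
  map <- run$map
  id4 <- map$cells$id[map$cells$row_label == "4" & map$cells$col == 3]
  bs4 <- bond_summary(run$bonds, id4)
  # T2-abutting membrane of a row 4 cell: own-Ds majority
  t2seg <- bs4[bs4$axis == "ap" & bs4$neighbour_row == "T2", ]
  expect_true(all(t2seg$majority == "Ds"))
  id3 <- map$cells$id[map$cells$row_label == "3" & map$cells$col == 3]
  bs3 <- bond_summary(run$bonds, id3)
  # row2|row3 interface: own-Ds majority on the row-3 side
  r2seg <- bs3[bs3$axis == "ap" & bs3$neighbour_row == "2", ]
  expect_true(all(r2seg$majority == "Ds"))
  # row3|row4 interface: balanced, and more balanced than the two above
  r4seg <- bs3[bs3$axis == "ap" & bs3$neighbour_row == "4", ]
  expect_true(all(r4seg$majority == "balanced"))
  imb <- function(d) abs(mean(d$own_ds) - mean(d$own_ft)) /
    (mean(d$own_ds) + mean(d$own_ft))
  expect_lt(imb(r4seg), imb(r2seg))
  expect_lt(imb(r4seg), imb(t2seg) / 2)
  expect_error(bond_summary(run$bonds, 99999), "unknown cell")
})

test_that("relaxation on mirrored tissue gives mirrored bonds", {
  map <- build_segment_map(n_columns = 2, trailing_p = TRUE)
  st <- compute_activities(assign_expression(map))
  b <- relax_bonds(initialise_bonds(map, st))
  mm <- mirror_map(map)
  stm <- compute_activities(assign_expression(mm))
  bm <- relax_bonds(initialise_bonds(mm, stm))
  # pick the T2|row4 interface of the middle column; in the mirrored map the
  # same two cells meet with sides exchanged
  id4 <- map$cells$id[map$cells$row_label == "4" & map$cells$col == 1]
  idT <- map$cells$id[map$cells$row_label == "T2" & map$cells$col == 1]
  s <- b$seg[!is.na(b$seg$cell_b) & b$seg$cell_a == id4 & b$seg$cell_b == idT, ]
  sm <- bm$seg[!is.na(bm$seg$cell_b) & bm$seg$cell_a == idT & bm$seg$cell_b == id4, ]
  expect_equal(nrow(s), nrow(sm))
  expect_lt(max(abs(sort(s$bond_ab) - sort(sm$bond_ba))), 1e-8)
  expect_lt(max(abs(sort(s$bond_ba) - sort(sm$bond_ab))), 1e-8)
})
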
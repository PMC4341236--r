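test_that("default segment map has the canonical row anatomy", {
  map <- build_segment_map()
  labs <- unique(map$cells$row_label)
  expect_setequal(setdiff(labs, c("P", "T1", "T2")), as.character(0:6))
  expect_equal(sum(map$cells$is_tendon), 2 * map$n_columns)
  expect_true(check_tessellation(map))
  # single column: 10 cells, 9 anterior-posterior interfaces
  m1 <- build_segment_map(n_columns = 1)
  expect_equal(nrow(m1$cells), 10)
  ap <- m1$segments[m1$segments$axis == "ap" & !is.na(m1$segments$cell_b), ]
  expect_equal(length(unique(paste(ap$cell_a, ap$cell_b))), 9)
  # a trailing P row closes the posterior border
  m2 <- build_segment_map(n_columns = 1, trailing_p = TRUE)
  expect_equal(nrow(m2$cells), 11)
  expect_equal(m2$cells$row_label[11], "P")
})

test_that("map configuration errors name the offending field", {
  expect_error(build_segment_map(n_columns = 0), "n_columns")
  expect_error(build_segment_map(cell_size = -1), "cell_size")
})

test_that("interface segments are consistent with the geometry", {
  map <- build_segment_map(n_columns = 3)
  seg <- map$segments
  # segment lengths sum to the shared boundary length (30 um contacts)
  int <- seg[!is.na(seg$cell_b), ]
  bylen <- tapply(int$length, paste(int$cell_a, int$cell_b, int$axis), sum)
  expect_true(all(abs(bylen - map$cell_size) < 1e-6))
  # orientation tags on the two sides are opposite along x
  ap <- int[int$axis == "ap", ]
  expect_true(all(ap$a_faces == "posterior" & ap$b_faces == "anterior"))
  # every cell-cell contact is discretised into at least 2 sub-segments
  expect_true(all(table(paste(int$cell_a, int$cell_b, int$axis)) >= 2))
  # neighbour relation is symmetric
  for (id in map$cells$id) {
    for (nb in neighbours(map, id)) {
      expect_true(id %in% neighbours(map, nb))
    }
  }
})

test_that("atypical reshaping creates the two-row neighbour pattern", {
  map <- build_segment_map(n_columns = 4, trailing_p = TRUE)
  m4 <- insert_atypical_cell(map, "4", col = 2)
  at <- m4$cells$id[m4$cells$is_atypical]
  expect_length(at, 1)
  post <- sort(unique(row_of(m4, neighbours(m4, at, side = "posterior"))))
  ant <- unique(row_of(m4, neighbours(m4, at, side = "anterior")))
  expect_equal(post, c("4", "T2"))
  expect_equal(ant, "3")
  expect_true(check_tessellation(m4))

  m2 <- insert_atypical_cell(map, "2", col = 2)
  at2 <- m2$cells$id[m2$cells$is_atypical]
  expect_setequal(row_of(m2, neighbours(m2, at2, side = "anterior")), c("T1", "2"))
  expect_equal(unique(row_of(m2, neighbours(m2, at2, side = "posterior"))), "3")
  expect_true(check_tessellation(m2))

  m3 <- insert_atypical_cell(map, "3", col = 2)
  at3 <- m3$cells$id[m3$cells$is_atypical]
  expect_setequal(row_of(m3, neighbours(m3, at3, side = "anterior")), c("2", "3"))
  expect_equal(unique(row_of(m3, neighbours(m3, at3, side = "posterior"))), "4")

  # zero tilt leaves the map untouched
  m0 <- insert_atypical_cell(map, "4", col = 2, promontory_height = 0)
  expect_identical(m0, map)
  # geometry that would break the tessellation errors
  expect_error(insert_atypical_cell(map, "4", col = 2, promontory_depth = 40),
               "geometry")
})

test_that("tendon gaps insert a filler with the flanking-row neighbours", {
  map <- build_segment_map(n_columns = 5, trailing_p = TRUE)
  g1 <- insert_tendon_gap(map, "T1", width = 1)
  f1 <- g1$cells$id[g1$cells$is_gap_filler]
  expect_equal(unique(row_of(g1, neighbours(g1, f1, side = "anterior"))), "1")
  expect_equal(unique(row_of(g1, neighbours(g1, f1, side = "posterior"))), "3")
  g2 <- insert_tendon_gap(map, "T2", width = 1)
  f2 <- g2$cells$id[g2$cells$is_gap_filler]
  expect_equal(unique(row_of(g2, neighbours(g2, f2, side = "anterior"))), "4")
  expect_equal(unique(row_of(g2, neighbours(g2, f2, side = "posterior"))), "6")
  expect_true(check_tessellation(g2))
  expect_error(insert_tendon_gap(map, "T1", width = 5), "width")
})

test_that("clone marking is connected, bounded and reproducible", {
  map <- build_segment_map(n_columns = 5)
  m2 <- mark_clone(map, seed = 42, size = 2)
  ids <- m2$cells$id[m2$cells$ectods_clone]
  expect_length(ids, 2)
  expect_true(ids[2] %in% neighbours(m2, ids[1]))
  expect_false(any(m2$cells$is_tendon[m2$cells$ectods_clone]))
  # same seed, same clone
  m2b <- mark_clone(map, seed = 42, size = 2)
  expect_identical(m2b$cells$ectods_clone, m2$cells$ectods_clone)
  # single cell
  m1 <- mark_clone(map, seed = 1, size = 1)
  expect_equal(sum(m1$cells$ectods_clone), 1)
  # default size distribution stays in 1..5
  sizes <- vapply(1:100, function(s)
    sum(mark_clone(map, seed = s)$cells$ectods_clone), numeric(1))
  expect_true(all(sizes >= 1 & sizes <= 5))
  expect_error(mark_clone(map, seed = 1, size = 6), "size")
  expect_equal(sum(mark_clone(map, seed = 1, size = 6,
                              allow_large = TRUE)$cells$ectods_clone), 6)
})

test_that("cell maps round-trip through JSON exactly", {
  map <- insert_atypical_cell(build_segment_map(n_columns = 3, trailing_p = TRUE),
                              "4", col = 1)
  map <- mark_clone(map, seed = 7, size = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cell_map(map, path)
  back <- read_cell_map(path)
  expect_identical(back$cells, map$cells)
  expect_equal(back$polygons, map$polygons)
  expect_identical(back$segments, map$segments)
})

test_that("mirroring reverses the anterior-posterior axis", {
  map <- build_segment_map(n_columns = 2, trailing_p = TRUE)
  mm <- mirror_map(map)
  expect_true(check_tessellation(mm))
  # the posterior neighbour of a cell becomes its anterior neighbour
  id <- map$cells$id[map$cells$row_label == "3" & map$cells$col == 1]
  post <- sort(neighbours(map, id, side = "posterior"))
  expect_equal(sort(neighbours(mm, id, side = "anterior")), post)
})
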
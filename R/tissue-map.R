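# ---------------------------------------------------------------------------
# Synthetic tissue maps of the larval ventral abdominal segment.
#
# Coordinates: x increases from anterior to posterior, y is mediolateral,
# units are micrometres.  Cell outlines are simple rectilinear polygons with
# counter-clockwise vertex order, so every edge is axis-aligned and the
# outward normal is recoverable from the direction of travel.
# ---------------------------------------------------------------------------

ROW_STACK <- c("P", "0", "1", "T1", "2", "3", "4", "T2", "5", "6")
TENDON_ROWS <- c("T1", "T2")
DENTICLE_ROWS <- as.character(0:6)

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

#' Build a brick-lattice cell map of the ventral larval segment
#'
#' Generates one or more segments of the ventral abdominal epidermis as an
#' aligned rectangular lattice.  Each segment is a stack of ten rows along
#' the anterior--posterior axis: the posterior-compartment row `P`, denticle
#' rows `0` and `1`, the tendon row `T1`, denticle rows `2`--`4`, the tendon
#' row `T2`, and denticle rows `5` and `6`.  Cells default to 30 um across,
#' the approximate size of third-stage epidermal cells.
#'
#' @param n_columns Number of cells per row along the mediolateral axis.
#' @param n_segments Number of repeated segments along the A--P axis.
#' @param cell_size Cell width and depth in micrometres.
#' @param seg_len Target length (um) of boundary sub-segments; every
#'   cell--cell contact is discretised into at least two sub-segments.
#' @param trailing_p If `TRUE`, append the anterior `P` row of the next
#'   segment after the last row 6, so that row 6 cells have a posterior
#'   neighbour instead of a map edge.
#' @return A `cell_map` object: cell table, polygon list and the discretised
#'   interface segment table.
#' @export
build_segment_map <- function(n_columns = 5, n_segments = 1, cell_size = 30,
                              seg_len = 2, trailing_p = FALSE) {
  if (!is.numeric(n_columns) || n_columns < 1) config_error("n_columns", "must be >= 1")
  if (!is.numeric(n_segments) || n_segments < 1) config_error("n_segments", "must be >= 1")
  if (!is.numeric(cell_size) || cell_size <= 0) config_error("cell_size", "must be > 0")
  if (!is.numeric(seg_len) || seg_len <= 0) config_error("seg_len", "must be > 0")
  n_columns <- as.integer(n_columns)
  n_segments <- as.integer(n_segments)

  labels <- rep(ROW_STACK, n_segments)
  if (trailing_p) labels <- c(labels, "P")
  n_rows <- length(labels)

  ids <- integer(0); row_label <- character(0); col <- integer(0)
  polygons <- list()
  w <- cell_size
  for (r in seq_len(n_rows)) {
    x0 <- (r - 1) * w; x1 <- r * w
    for (cc in seq_len(n_columns)) {
      y0 <- (cc - 1) * w; y1 <- cc * w
      id <- (r - 1L) * n_columns + cc
      ids <- c(ids, id)
      row_label <- c(row_label, labels[r])
      col <- c(col, cc)
      polygons[[as.character(id)]] <- rect_poly(x0, y0, x1, y1)
    }
  }
  cells <- data.frame(
    id = ids, row_label = row_label, col = col,
    is_tendon = row_label %in% TENDON_ROWS,
    is_atypical = FALSE, is_gap_filler = FALSE,
    ds_null = FALSE, ft_null = FALSE, ectods_clone = FALSE,
    stringsAsFactors = FALSE
  )
  map <- structure(list(
    cells = cells, polygons = polygons,
    cell_size = cell_size, seg_len = seg_len,
    n_columns = n_columns, n_segments = n_segments, trailing_p = trailing_p,
    axis = "x: anterior -> posterior (um); y: mediolateral (um)"
  ), class = "cell_map")
  map$segments <- build_interfaces(map)
  map
}

rect_poly <- function(x0, y0, x1, y1) {
  matrix(c(x0, y0, x1, y0, x1, y1, x0, y1), ncol = 2, byrow = TRUE)
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> %d cells (%d tendon), %d interface segments\n",
              nrow(x$cells), sum(x$cells$is_tendon),
              sum(!is.na(x$segments$cell_b))))
  cat(sprintf("  rows: %s\n", paste(unique(x$cells$row_label), collapse = " ")))
  cat(" ", x$axis, "\n")
  invisible(x)
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

# Edges of a CCW rectilinear polygon with outward-normal codes.
# Returns data.frame(x0,y0,x1,y1, vertical, outward) where outward is
# +1/-1 along the edge's normal axis.
polygon_edges <- function(poly) {
  n <- nrow(poly)
  nx <- poly[c(2:n, 1), 1]; ny <- poly[c(2:n, 1), 2]
  dx <- nx - poly[, 1]; dy <- ny - poly[, 2]
  vertical <- abs(dx) < 1e-12
  outward <- ifelse(vertical, ifelse(dy > 0, 1L, -1L), ifelse(dx > 0, -1L, 1L))
  data.frame(x0 = poly[, 1], y0 = poly[, 2], x1 = nx, y1 = ny,
             vertical = vertical, outward = outward)
}

# Discretise shared boundaries between all cell polygons into sub-segments.
# For A-P ("ap") segments cell_a is the anterior cell (its posterior-facing
# membrane); for mediolateral ("ml") segments side assignment is arbitrary
# and both sides are tagged lateral.  Unmatched edge portions become border
# segments with cell_b = NA.
build_interfaces <- function(map) {
  seg_len <- map$seg_len
  ids <- map$cells$id
  ve <- list(); he <- list()
  for (i in seq_along(ids)) {
    ed <- polygon_edges(map$polygons[[as.character(ids[i])]])
    ed$cell <- ids[i]
    ve[[i]] <- ed[ed$vertical, ]
    he[[i]] <- ed[!ed$vertical, ]
  }
  ve <- do.call(rbind, ve); he <- do.call(rbind, he)
  ve$pos <- round(ve$x0, 9)
  ve$lo <- pmin(ve$y0, ve$y1); ve$hi <- pmax(ve$y0, ve$y1)
  he$pos <- round(he$y0, 9)
  he$lo <- pmin(he$x0, he$x1); he$hi <- pmax(he$x0, he$x1)

  out <- list(); k <- 0L
  add <- function(cell_a, cell_b, axis, pos, lo, hi, a_faces, b_faces, min_seg) {
    len <- hi - lo
    if (len <= 1e-9) return(invisible(NULL))
    nseg <- max(min_seg, ceiling(len / seg_len - 1e-9))
    br <- seq(lo, hi, length.out = nseg + 1)
    k <<- k + 1L
    out[[k]] <<- data.frame(
      iface = k, cell_a = cell_a, cell_b = cell_b, axis = axis, pos = pos,
      lo = br[-length(br)], hi = br[-1],
      a_faces = a_faces, b_faces = b_faces, stringsAsFactors = FALSE
    )
    invisible(NULL)
  }

  match_axis <- function(ed, axis) {
    for (p in unique(ed$pos)) {
      sub <- ed[ed$pos == p, ]
      plus <- sub[sub$outward > 0, ]   # outward toward +x (posterior) / +y
      minus <- sub[sub$outward < 0, ]
      covered_plus <- vector("list", nrow(plus))
      covered_minus <- vector("list", nrow(minus))
      if (nrow(plus) && nrow(minus)) {
        for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
          lo <- max(plus$lo[i], minus$lo[j]); hi <- min(plus$hi[i], minus$hi[j])
          if (hi - lo > 1e-9) {
            if (axis == "ap") {
              add(plus$cell[i], minus$cell[j], "ap", p, lo, hi,
                  "posterior", "anterior", 2L)
            } else {
              add(plus$cell[i], minus$cell[j], "ml", p, lo, hi,
                  "lateral", "lateral", 2L)
            }
            covered_plus[[i]] <- rbind(covered_plus[[i]], c(lo, hi))
            covered_minus[[j]] <- rbind(covered_minus[[j]], c(lo, hi))
          }
        }
      }
      emit_border <- function(rows, covered, faces_plus, faces_minus) {
        for (i in seq_len(nrow(rows))) {
          gaps <- interval_complement(rows$lo[i], rows$hi[i], covered[[i]])
          faces <- if (rows$outward[i] > 0) faces_plus else faces_minus
          for (g in seq_len(nrow(gaps))) {
            add(rows$cell[i], NA_integer_, axis, p, gaps[g, 1], gaps[g, 2],
                faces, NA_character_, 1L)
          }
        }
      }
      if (axis == "ap") {
        emit_border(plus, covered_plus, "posterior", "anterior")
        emit_border(minus, covered_minus, "posterior", "anterior")
      } else {
        emit_border(plus, covered_plus, "lateral", "lateral")
        emit_border(minus, covered_minus, "lateral", "lateral")
      }
    }
  }
  match_axis(ve, "ap")
  match_axis(he, "ml")
  seg <- do.call(rbind, out)
  seg <- seg[order(seg$axis, seg$pos, seg$lo, seg$cell_a), ]
  seg$seg <- seq_len(nrow(seg))
  seg$length <- seg$hi - seg$lo
  seg$mid <- (seg$lo + seg$hi) / 2
  rownames(seg) <- NULL
  seg[, c("seg", "iface", "cell_a", "cell_b", "axis", "pos", "lo", "hi",
          "mid", "length", "a_faces", "b_faces")]
}

# Complement of a union of sub-intervals within [lo, hi].
interval_complement <- function(lo, hi, covered) {
  if (is.null(covered)) return(matrix(c(lo, hi), ncol = 2))
  covered <- covered[order(covered[, 1]), , drop = FALSE]
  out <- NULL; cur <- lo
  for (i in seq_len(nrow(covered))) {
    if (covered[i, 1] - cur > 1e-9) out <- rbind(out, c(cur, covered[i, 1]))
    cur <- max(cur, covered[i, 2])
  }
  if (hi - cur > 1e-9) out <- rbind(out, c(cur, hi))
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

#' Neighbouring cells of a cell
#'
#' @param map A `cell_map`.
#' @param id Cell id.
#' @param side Optional: restrict to cells abutting the `"anterior"` or
#'   `"posterior"` membrane (A--P axis) or `"lateral"` contacts.
#' @return Integer vector of neighbouring cell ids.
#' @export
neighbours <- function(map, id, side = NULL) {
  seg <- map$segments
  a <- seg$cell_a == id
  b <- !is.na(seg$cell_b) & seg$cell_b == id
  if (!is.null(side)) {
    side <- match.arg(side, c("anterior", "posterior", "lateral"))
    a <- a & seg$a_faces == side
    b <- b & seg$b_faces == side
  }
  unique(c(seg$cell_b[a & !is.na(seg$cell_b)], seg$cell_a[b]))
}

row_of <- function(map, ids) map$cells$row_label[match(ids, map$cells$id)]

find_cell <- function(map, row_label, col) {
  hit <- map$cells$id[map$cells$row_label == row_label & map$cells$col == col]
  if (length(hit) != 1)
    stop(sprintf("no unique cell with row_label=%s col=%d", row_label, col),
         call. = FALSE)
  hit
}

#' Reshape one cell into an "atypical", two-row-spanning cell
#'
#' A cell of the target row acquires a rectangular promontory that invades
#' the territory of its mediolateral neighbour, so that part of the cell
#' contacts neighbours of a different type.  For row 4 the promontory sits in
#' the anterior part of the row band, so the reshaped cell has posterior
#' neighbours of two types (the T2 tendon cell and a normal row 4 cell) while
#' all anterior neighbours remain row 3.  For rows 2 and 3 the promontory
#' sits posteriorly (anterior neighbours T1+row2, respectively row2+row3).
#'
#' @param map A wild-type `cell_map`.
#' @param target_row `"2"`, `"3"` or `"4"`.
#' @param col Mediolateral column of the cell to reshape (default: middle).
#' @param promontory_height Mediolateral extent (um) of the promontory into
#'   the neighbouring column; `0` returns the map unchanged.
#' @param promontory_depth A--P depth (um) of the promontory
#'   (default: half the cell size).
#' @return The modified `cell_map`.
#' @export
insert_atypical_cell <- function(map, target_row, col = NULL,
                                 promontory_height = 10,
                                 promontory_depth = NULL) {
  target_row <- as.character(target_row)
  if (!target_row %in% c("2", "3", "4"))
    config_error("target_row", "must be one of 2, 3, 4")
  w <- map$cell_size
  if (is.null(promontory_depth)) promontory_depth <- w / 2
  if (promontory_height == 0) return(map)
  if (promontory_height < 0 || promontory_height > w)
    stop("geometry error: promontory_height must lie in [0, cell_size]",
         call. = FALSE)
  if (promontory_depth <= 0 || promontory_depth >= w)
    stop("geometry error: promontory_depth must lie in (0, cell_size)",
         call. = FALSE)
  if (is.null(col)) col <- max(1L, floor((map$n_columns) / 2))
  if (col + 1 > map$n_columns)
    stop("geometry error: atypical cell needs a neighbouring column",
         call. = FALSE)

  a_id <- find_cell(map, target_row, col)
  n_id <- find_cell(map, target_row, col + 1)
  pa <- map$polygons[[as.character(a_id)]]
  x0 <- min(pa[, 1]); x1 <- max(pa[, 1])
  y0 <- min(pa[, 2]); y1 <- max(pa[, 2])
  y2 <- y1 + promontory_height
  pn <- map$polygons[[as.character(n_id)]]
  y3 <- max(pn[, 2])
  if (y2 > y3 + 1e-9)
    stop("geometry error: promontory exceeds the neighbouring column",
         call. = FALSE)

  if (target_row == "4") {
    xm <- x0 + promontory_depth
    poly_a <- matrix(c(x0, y0, x1, y0, x1, y1, xm, y1, xm, y2, x0, y2),
                     ncol = 2, byrow = TRUE)
    poly_n <- matrix(c(xm, y1, x1, y1, x1, y3, x0, y3, x0, y2, xm, y2),
                     ncol = 2, byrow = TRUE)
  } else {
    xm <- x1 - promontory_depth
    poly_a <- matrix(c(x0, y0, x1, y0, x1, y2, xm, y2, xm, y1, x0, y1),
                     ncol = 2, byrow = TRUE)
    poly_n <- matrix(c(x0, y1, xm, y1, xm, y2, x1, y2, x1, y3, x0, y3),
                     ncol = 2, byrow = TRUE)
  }
  map$polygons[[as.character(a_id)]] <- poly_a
  map$polygons[[as.character(n_id)]] <- poly_n
  map$cells$is_atypical[map$cells$id == a_id] <- TRUE
  map$segments <- build_interfaces(map)
  map
}

#' Open a gap in a tendon row
#'
#' Removes `width` tendon cells and lets the abutting posterior denticulate
#' cell (row 2 for a T1 gap, row 5 for a T2 gap) expand anteriorly into the
#' breach.  The expanded filler cell then lies between a row 1 and a row 3
#' cell (T1 gap), or between a row 4 and a row 6 cell (T2 gap) -- neighbours
#' with near-identical Ds activity, hence no directional cue.
#'
#' @param map A `cell_map`.
#' @param tendon_row `"T1"` or `"T2"`.
#' @param col First mediolateral column of the gap (default: middle).
#' @param width Gap width in cells; must be smaller than the row length.
#' @return The modified `cell_map`; filler cells carry `is_gap_filler`.
#' @export
insert_tendon_gap <- function(map, tendon_row, col = NULL, width = 1) {
  tendon_row <- as.character(tendon_row)
  if (!tendon_row %in% TENDON_ROWS) config_error("tendon_row", "must be T1 or T2")
  if (width < 1) config_error("width", "must be >= 1")
  if (width >= map$n_columns)
    config_error("width", "must be smaller than the number of cells in the row")
  if (is.null(col)) col <- max(1L, floor((map$n_columns - width) / 2) + 1L)
  if (col + width - 1 > map$n_columns)
    config_error("col", "gap extends beyond the row")
  filler_row <- if (tendon_row == "T1") "2" else "5"
  for (cc in col:(col + width - 1)) {
    t_id <- find_cell(map, tendon_row, cc)
    f_id <- find_cell(map, filler_row, cc)
    pt <- map$polygons[[as.character(t_id)]]
    pf <- map$polygons[[as.character(f_id)]]
    x0 <- min(pt[, 1]); x1 <- max(pf[, 1])
    y0 <- min(pf[, 2]); y1 <- max(pf[, 2])
    map$polygons[[as.character(f_id)]] <- rect_poly(x0, y0, x1, y1)
    map$polygons[[as.character(t_id)]] <- NULL
    map$cells <- map$cells[map$cells$id != t_id, ]
    map$cells$is_gap_filler[map$cells$id == f_id] <- TRUE
  }
  rownames(map$cells) <- NULL
  map$segments <- build_interfaces(map)
  map
}

#' Mark a small Ds-overexpressing clone
#'
#' Flags a connected set of 1--5 non-tendon cells as `ectods_clone`,
#' mimicking the small clones induced at the blastoderm stage.  The default
#' clone size is drawn uniformly from 1--5 cells.
#'
#' @param map A `cell_map`.
#' @param seed Optional integer seed; the draw is reproducible given the seed.
#' @param size Clone size in cells (1--5), or `NULL` to draw from the default
#'   distribution.
#' @param start Optional starting cell id (must be non-tendon).
#' @param allow_large Permit sizes above 5 (not observed in vivo).
#' @return The modified `cell_map`.
#' @export
mark_clone <- function(map, seed = NULL, size = NULL, start = NULL,
                       allow_large = FALSE) {
  with_local_seed(seed, {
    if (is.null(size)) size <- sample.int(5L, 1L)
    if (size < 1) config_error("size", "must be >= 1")
    if (size > 5 && !allow_large)
      config_error("size", "exceeds 5, the largest clone size observed in vivo (set allow_large = TRUE to override)")
    eligible <- map$cells$id[!map$cells$is_tendon]
    if (is.null(start)) {
      start <- sample(eligible, 1L)
    } else if (!start %in% eligible) {
      config_error("start", "must be an existing non-tendon cell id")
    }
    clone <- start
    while (length(clone) < size) {
      frontier <- setdiff(
        intersect(unique(unlist(lapply(clone, neighbours, map = map))), eligible),
        clone
      )
      if (length(frontier) == 0) break
      clone <- c(clone, frontier[sample.int(length(frontier), 1L)])
    }
    map$cells$ectods_clone[map$cells$id %in% clone] <- TRUE
    map
  })
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (or under the current stream if seed is NULL).
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Mirror a map along the anterior--posterior axis
#'
#' Reflects all cell outlines so that anterior and posterior are exchanged;
#' used for the polarity antisymmetry checks.
#'
#' @param map A `cell_map`.
#' @return The mirrored `cell_map`.
#' @export
mirror_map <- function(map) {
  xmax <- max(vapply(map$polygons, function(p) max(p[, 1]), numeric(1)))
  xmin <- min(vapply(map$polygons, function(p) min(p[, 1]), numeric(1)))
  for (nm in names(map$polygons)) {
    p <- map$polygons[[nm]]
    p[, 1] <- xmax + xmin - p[, 1]
    map$polygons[[nm]] <- p[rev(seq_len(nrow(p))), ]  # restore CCW
  }
  map$segments <- build_interfaces(map)
  map
}

# Even-odd point-in-polygon, vectorised over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Audit that a map's cells tile the plane
#'
#' Checks that cell polygons are simple, positively oriented, and cover the
#' map without overlaps or interior holes (by exact area accounting and a
#' coverage raster at `res` micrometres).
#'
#' @param map A `cell_map`.
#' @param res Raster resolution in micrometres.
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
check_tessellation <- function(map, res = 2.5) {
  areas <- vapply(map$polygons, polygon_area, numeric(1))
  if (any(areas <= 0)) stop("tessellation error: non-CCW or degenerate polygon")
  xs <- unlist(lapply(map$polygons, function(p) range(p[, 1])))
  ys <- unlist(lapply(map$polygons, function(p) range(p[, 2])))
  px <- seq(min(xs) + res / 2, max(xs) - res / 2, by = res)
  py <- seq(min(ys) + res / 2, max(ys) - res / 2, by = res)
  grid <- expand.grid(x = px, y = py)
  count <- rep(0L, nrow(grid))
  for (p in map$polygons)
    count <- count + point_in_polygon(grid$x, grid$y, p)
  if (any(count > 1)) stop("tessellation error: overlapping cell polygons")
  # holes are permitted only where cells were removed; for intact maps the
  # area accounting below catches them
  tot <- sum(areas)
  bbox <- (max(xs) - min(xs)) * (max(ys) - min(ys))
  hole_area <- bbox - tot
  n_uncovered <- sum(count == 0)
  if (abs(n_uncovered * res^2 - hole_area) > bbox * 0.02 + res^2 * 4)
    stop("tessellation error: unexpected uncovered area")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Serialisation: GeoJSON-style polygon arrays plus per-cell properties.
# ---------------------------------------------------------------------------

#' Write a cell map to JSON
#'
#' @param map A `cell_map`.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_cell_map <- function(map, path) {
  cells <- lapply(seq_len(nrow(map$cells)), function(i) {
    r <- map$cells[i, ]
    poly <- map$polygons[[as.character(r$id)]]
    list(
      id = r$id,
      properties = list(
        row_label = r$row_label, col = r$col,
        is_tendon = r$is_tendon, is_atypical = r$is_atypical,
        is_gap_filler = r$is_gap_filler,
        genotype = list(ds_null = r$ds_null, ft_null = r$ft_null,
                        ectods_clone = r$ectods_clone)
      ),
      polygon = unname(lapply(seq_len(nrow(poly)), function(k) poly[k, ]))
    )
  })
  doc <- list(
    format = "conduitpcp-cellmap", version = 1L, axis = map$axis,
    cell_size = map$cell_size, seg_len = map$seg_len,
    n_columns = map$n_columns, n_segments = map$n_segments,
    trailing_p = map$trailing_p, cells = cells
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cell map from JSON
#'
#' @param path File written by [write_cell_map()].
#' @return A `cell_map`; interface segments are rebuilt from the geometry.
#' @export
read_cell_map <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "conduitpcp-cellmap"))
    stop("not a conduitpcp cell map file", call. = FALSE)
  n <- length(doc$cells)
  cells <- data.frame(
    id = vapply(doc$cells, function(cl) as.integer(cl$id), integer(1)),
    row_label = vapply(doc$cells, function(cl) cl$properties$row_label, character(1)),
    col = vapply(doc$cells, function(cl) as.integer(cl$properties$col), integer(1)),
    is_tendon = vapply(doc$cells, function(cl) cl$properties$is_tendon, logical(1)),
    is_atypical = vapply(doc$cells, function(cl) cl$properties$is_atypical, logical(1)),
    is_gap_filler = vapply(doc$cells, function(cl) cl$properties$is_gap_filler, logical(1)),
    ds_null = vapply(doc$cells, function(cl) cl$properties$genotype$ds_null, logical(1)),
    ft_null = vapply(doc$cells, function(cl) cl$properties$genotype$ft_null, logical(1)),
    ectods_clone = vapply(doc$cells, function(cl) cl$properties$genotype$ectods_clone, logical(1)),
    stringsAsFactors = FALSE
  )
  polygons <- list()
  for (cl in doc$cells) {
    poly <- do.call(rbind, lapply(cl$polygon, function(v) c(v[[1]], v[[2]])))
    polygons[[as.character(cl$id)]] <- poly
  }
  map <- structure(list(
    cells = cells, polygons = polygons,
    cell_size = doc$cell_size, seg_len = doc$seg_len,
    n_columns = doc$n_columns, n_segments = doc$n_segments,
    trailing_p = doc$trailing_p, axis = doc$axis
  ), class = "cell_map")
  map$segments <- build_interfaces(map)
  map
}
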
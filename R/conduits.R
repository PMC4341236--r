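# ---------------------------------------------------------------------------
# Conduits: facing anterior/posterior membrane subregions of one cell.
#
# Each non-tendon cell is sliced into mediolateral bands; every band whose
# anterior and posterior membranes both abut a neighbour yields one conduit.
# A conduit's polarity is the local comparison of bridge composition between
# its two membrane subregions: denticles point towards the membrane with
# more own-Ft bridges, i.e. towards the neighbour presenting more Ds.
# Because different bands can abut different neighbours, one cell can carry
# conduits of opposite sign: a multipolar cell.
# ---------------------------------------------------------------------------

#' Build conduits for every non-tendon cell
#'
#' @param map A `cell_map`.
#' @param bonds A relaxed `bond_state` for the map.
#' @param band_width Mediolateral band width in micrometres (default 5, so a
#'   30 um cell carries six conduits and even a small atypical promontory
#'   gets its own).
#' @return A `conduit_set` data.frame: one row per conduit with the cell id,
#'   band interval, the abutting neighbour row labels on each side, and
#'   segment references used later for scoring.
#' @export
build_conduits <- function(map, bonds, band_width = 5) {
  if (!is.numeric(band_width) || band_width <= 0)
    config_error("band_width", "must be > 0")
  seg <- bonds$seg
  ap <- seg$axis == "ap" & !is.na(seg$cell_b)
  rows <- list(); k <- 0L
  for (id in map$cells$id[!map$cells$is_tendon]) {
    poly <- map$polygons[[as.character(id)]]
    ymin <- min(poly[, 2]); ymax <- max(poly[, 2])
    nb <- max(1L, ceiling((ymax - ymin) / band_width - 1e-9))
    br <- seq(ymin, ymax, length.out = nb + 1)

    side_a <- which(ap & seg$cell_a == id)
    side_b <- which(ap & seg$cell_b == id)
    idxs <- c(side_a, side_b)
    sides <- c(rep("a", length(side_a)), rep("b", length(side_b)))
    faces <- c(seg$a_faces[side_a], seg$b_faces[side_b])
    nbrs <- c(seg$cell_b[side_a], seg$cell_a[side_b])
    lo <- seg$lo[idxs]; hi <- seg$hi[idxs]

    for (b in seq_len(nb)) {
      b0 <- br[b]; b1 <- br[b + 1]
      ov <- pmin(hi, b1) - pmax(lo, b0)
      sel <- ov > 1e-9
      ant <- sel & faces == "anterior"
      post <- sel & faces == "posterior"
      if (!any(ant) || !any(post)) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        conduit = k, cell = id, band = b, y0 = b0, y1 = b1,
        ant_labels = paste(sort(unique(row_of(map, nbrs[ant]))), collapse = "+"),
        post_labels = paste(sort(unique(row_of(map, nbrs[post]))), collapse = "+"),
        ant_refs = I(list(list(idx = idxs[ant], side = sides[ant], w = ov[ant]))),
        post_refs = I(list(list(idx = idxs[post], side = sides[post], w = ov[post]))),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(conduit = integer(0), cell = integer(0))
  class(out) <- c("conduit_set", "data.frame")
  out
}

own_ft_density <- function(seg, refs) {
  dens <- ifelse(refs$side == "a", seg$bond_ba[refs$idx], seg$bond_ab[refs$idx])
  sum(dens * refs$w) / sum(refs$w)
}

own_ds_density <- function(seg, refs) {
  dens <- ifelse(refs$side == "a", seg$bond_ab[refs$idx], seg$bond_ba[refs$idx])
  sum(dens * refs$w) / sum(refs$w)
}

# Own-Ft share of all bridges on one membrane subregion; 1/2 on a
# bridge-free membrane (no directional information).
own_ft_fraction <- function(seg, refs) {
  ft <- own_ft_density(seg, refs); ds <- own_ds_density(seg, refs)
  tot <- ft + ds
  if (tot < 1e-12) 0.5 else ft / tot
}

#' Score conduits and call per-subdomain polarity
#'
#' The polarity of a membrane subregion pair is read from the relative
#' bridge composition: the score is the own-Ft share of all bridges
#' (length-weighted) over the posterior membrane subregion minus that over
#' the anterior one, so a bridge-free membrane carries no directional
#' information (share 1/2) and the score lives in \[-1, 1\].  Denticles
#' point towards the side with the larger own-Ft share, i.e. towards the
#' neighbour presenting more Ds.  Calls: `anterior` if
#' `score < -theta`, `posterior` if `score > theta`, else `unpolarized`.
#' The default threshold is absolute on the composition scale: membrane
#' pairs whose own-Ft shares differ by two composition points or less carry
#' no reliable directional cue.  Alternatively `theta = NULL` derives the
#' threshold as `theta_frac` of the largest absolute score in the set.
#'
#' @param conduits A `conduit_set` from [build_conduits()].
#' @param bonds The relaxed `bond_state` the conduits were built on.
#' @param theta Unpolarized-call threshold on the share-difference scale;
#'   `NULL` to derive from `theta_frac`.
#' @param theta_frac Fraction of the maximum absolute score used for the
#'   threshold when `theta = NULL`.
#' @return The conduit set with `score`, `theta` and `call` columns.
#' @export
score_conduits <- function(conduits, bonds, theta = 0.02, theta_frac = 0.02) {
  if (nrow(conduits) == 0) {
    conduits$score <- numeric(0); conduits$call <- character(0)
    return(conduits)
  }
  seg <- bonds$seg
  score <- vapply(seq_len(nrow(conduits)), function(i) {
    a <- conduits$ant_refs[[i]]; p <- conduits$post_refs[[i]]
    if (length(a$idx) == 0 || length(p$idx) == 0)
      stop("invalid conduit: empty segment set", call. = FALSE)
    own_ft_fraction(seg, p) - own_ft_fraction(seg, a)
  }, numeric(1))
  if (is.null(theta)) theta <- theta_frac * max(abs(score))
  conduits$score <- score
  conduits$theta <- theta
  conduits$call <- ifelse(score < -theta, "anterior",
                          ifelse(score > theta, "posterior", "unpolarized"))
  conduits
}

#' Classify whole-cell polarity from a cell's conduit calls
#'
#' A cell is `multipolar` when anterior and posterior conduit calls coexist,
#' `unpolarized` when every call is unpolarized (or it has no conduit at
#' all), otherwise unipolar in the direction of its calls.  Clone cells can
#' optionally be forced to `unpolarized`, reflecting the saturation of
#' directional bias in cells whose Ds activity towers over every neighbour.
#'
#' @param conduits Scored `conduit_set`.
#' @param map The `cell_map`.
#' @param force_clone_unpolarized Force `ectods_clone` cells to unpolarized.
#' @return data.frame: cell, row_label, n_conduits, calls per type, class.
#' @export
classify_cells <- function(conduits, map, force_clone_unpolarized = FALSE) {
  ids <- map$cells$id[!map$cells$is_tendon]
  res <- lapply(ids, function(id) {
    calls <- conduits$call[conduits$cell == id]
    n_ant <- sum(calls == "anterior"); n_post <- sum(calls == "posterior")
    cls <- if (length(calls) == 0) "unpolarized"
      else if (n_ant > 0 && n_post > 0) "multipolar"
      else if (n_ant > 0) "unipolar_anterior"
      else if (n_post > 0) "unipolar_posterior"
      else "unpolarized"
    data.frame(cell = id, row_label = row_of(map, id),
               n_conduits = length(calls), n_anterior = n_ant,
               n_posterior = n_post,
               n_unpolarized = sum(calls == "unpolarized"),
               class = cls, no_conduits = length(calls) == 0,
               forced = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (force_clone_unpolarized) {
    cl <- map$cells$ectods_clone[match(out$cell, map$cells$id)]
    out$forced <- cl & out$class != "unpolarized"
    out$class[cl] <- "unpolarized"
  }
  out
}

#' Place denticles according to conduit calls
#'
#' Polarized conduits put their denticles adjacent to the membrane the call
#' points towards, inheriting the call's orientation.  Unpolarized conduits
#' put them centrally (mid-cell) with orientation drawn uniformly from
#' anterior/posterior -- in a bond-free `ds- ft-` epidermis every denticle is
#' therefore an independent uniform draw.  The caller seeds the RNG; draws
#' consume the stream in cell-id order, so runs are reproducible.
#'
#' @param map A `cell_map`.
#' @param conduits Scored `conduit_set`.
#' @param count Denticles per conduit.
#' @param membrane_offset Distance (um) of membrane-adjacent denticles from
#'   the membrane.
#' @return A data.frame of denticles: cell, conduit, x, y, orientation,
#'   placement, and the conduit's side labels.
#' @export
place_denticles <- function(map, conduits, count = 1, membrane_offset = 1.5) {
  if (count < 0) config_error("count", "must be >= 0")
  seg <- NULL
  out <- list(); k <- 0L
  dent_cells <- map$cells$id[map$cells$row_label %in% DENTICLE_ROWS]
  for (id in sort(dent_cells)) {
    rows <- which(conduits$cell == id)
    if (length(rows) == 0) next
    cen <- polygon_centroid(map$polygons[[as.character(id)]])
    for (r in rows[order(conduits$band[rows])]) {
      if (count == 0) next
      call <- conduits$call[r]
      yc <- (conduits$y0[r] + conduits$y1[r]) / 2
      for (j in seq_len(count)) {
        k <- k + 1L
        if (call == "unpolarized") {
          ori <- sample(c("anterior", "posterior"), 1)
          out[[k]] <- data.frame(
            cell = id, conduit = conduits$conduit[r], x = cen[1], y = yc,
            orientation = ori, placement = "central",
            ant_labels = conduits$ant_labels[r],
            post_labels = conduits$post_labels[r], stringsAsFactors = FALSE)
        } else {
          refs <- if (call == "anterior") conduits$ant_refs[[r]] else conduits$post_refs[[r]]
          # membrane x position: weighted over the called side's segments
          xpos <- sum(map$segments$pos[refs$idx] * refs$w) / sum(refs$w)
          x <- if (call == "anterior") xpos + membrane_offset else xpos - membrane_offset
          out[[k]] <- data.frame(
            cell = id, conduit = conduits$conduit[r], x = x, y = yc,
            orientation = call, placement = "membrane",
            ant_labels = conduits$ant_labels[r],
            post_labels = conduits$post_labels[r], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0) {
    return(data.frame(cell = integer(0), conduit = integer(0), x = numeric(0),
                      y = numeric(0), orientation = character(0),
                      placement = character(0), ant_labels = character(0),
                      post_labels = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
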
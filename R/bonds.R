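# ---------------------------------------------------------------------------
# Ds-Ft heterodimer bridges on discretised cell-cell interfaces.
#
# Every interface segment s between cells x and y can carry two bridge
# species: Ds^x-Ft^y (Ds contributed by x) and Ft^x-Ds^y.  Each cell owns a
# fixed pool of Ds and Ft proportional to its activity; free (unbound)
# protein sits on the cell's boundary segments and is (i) consumed/released
# by mass-action-like binding against the facing neighbour's free partner
# and (ii) re-shuttled each iteration towards segments whose facing membrane
# presents more unbound partner.  The shuttle step is what lets a
# high-Ds membrane "draw" the neighbour's Ft (and vice versa) and thereby
# propagates polarity from cell to cell.  All quantities are densities per
# micrometre of membrane.
# ---------------------------------------------------------------------------

#' Initialise free protein pools on a map
#'
#' Each cell's Ds and Ft pools (mean activity times perimeter) are spread
#' over its boundary segments proportionally to segment length times the
#' local (anterior/posterior endpoint) activity, so a cell with a within-cell
#' gradient presents more Ds on the limit where its activity is higher.  No
#' bonds exist yet.
#'
#' @param map A `cell_map`.
#' @param activities An `activity_state` with `ds_act_*`/`ft_act_*` columns
#'   (see [compute_activities()] and [apply_genotype()]).
#' @return A `bond_state` object.
#' @export
initialise_bonds <- function(map, activities) {
  seg <- map$segments
  n <- nrow(seg)
  st <- list(map = map, activities = activities, seg = seg)
  for (cn in c("free_ds_a", "free_ft_a", "free_ds_b", "free_ft_b",
               "bond_ab", "bond_ba"))
    st$seg[[cn]] <- numeric(n)

  idx <- function(id) match(id, activities$id)
  local_val <- function(ids, faces, which) {
    i <- idx(ids)
    ant <- activities[[paste0(which, "_act_ant")]][i]
    post <- activities[[paste0(which, "_act_post")]][i]
    ifelse(faces == "anterior", ant, ifelse(faces == "posterior", post,
                                            (ant + post) / 2))
  }

  pools <- data.frame(id = activities$id)
  perim <- numeric(nrow(pools))
  for (k in seq_len(nrow(pools))) {
    id <- pools$id[k]
    perim[k] <- sum(seg$length[seg$cell_a == id]) +
      sum(seg$length[!is.na(seg$cell_b) & seg$cell_b == id])
  }
  pools$pool_ds <- (activities$ds_act_ant + activities$ds_act_post) / 2 * perim
  pools$pool_ft <- (activities$ft_act_ant + activities$ft_act_post) / 2 * perim
  pools$perimeter <- perim

  allocate <- function(which) {
    dens_a <- numeric(n); dens_b <- numeric(n)
    la <- local_val(seg$cell_a, seg$a_faces, which)
    has_b <- !is.na(seg$cell_b)
    lb <- numeric(n)
    lb[has_b] <- local_val(seg$cell_b[has_b], seg$b_faces[has_b], which)
    pool <- pools[[paste0("pool_", which)]]
    for (k in seq_len(nrow(pools))) {
      id <- pools$id[k]
      ra <- seg$cell_a == id
      rb <- has_b & seg$cell_b == id
      w <- sum(seg$length[ra] * la[ra]) + sum(seg$length[rb] * lb[rb])
      if (w > 1e-300) {
        dens_a[ra] <- pool[k] * la[ra] / w
        dens_b[rb] <- pool[k] * lb[rb] / w
      }
    }
    list(a = dens_a, b = dens_b)
  }
  ds <- allocate("ds"); ft <- allocate("ft")
  st$seg$free_ds_a <- ds$a; st$seg$free_ds_b <- ds$b
  st$seg$free_ft_a <- ft$a; st$seg$free_ft_b <- ft$b
  st$pools <- pools
  st$converged <- FALSE
  st$iterations <- 0L
  structure(st, class = "bond_state")
}

#' @export
print.bond_state <- function(x, ...) {
  cat(sprintf("<bond_state> %d segments, %d cells; iterations=%d converged=%s\n",
              nrow(x$seg), nrow(x$pools), x$iterations, x$converged))
  invisible(x)
}

#' Relax heterodimer bonds to a fixed point
#'
#' Synchronous deterministic iteration of two steps: (i) on every interior
#' segment, each bridge species moves towards its mass-action equilibrium
#' `bond = kb/ku * free_ds * free_ft` with damping `eta` and a cap of half
#' the limiting free pool per step (the default is a weak-binding regime,
#' in which bridge composition tracks the product of the two cells' local
#' activities rather than network-wide depletion); (ii) each cell
#' re-shuttles a fraction
#' `shuttle_frac` of each unbound protein across its own segments,
#' proportionally to the facing membrane's unbound partner.  Iterates until
#' the largest absolute bond-density change drops below `tol`.
#'
#' @param state A `bond_state` from [initialise_bonds()].
#' @param max_iter Iteration cap; non-convergence gives a warning and a
#'   flagged (not failed) result.
#' @param tol Convergence tolerance on bond densities.
#' @param kb,ku Binding / unbinding rate constants.
#' @param eta Damping factor of the binding step.
#' @param shuttle_frac Fraction of unbound protein redistributed per step.
#' @param draw Strength of the neighbour's pull: the shuttle weight of a
#'   segment is its length times `1 + draw * facing free partner density`.
#' @param record_conservation Record the per-iteration maximum conservation
#'   error in `$conservation_trace`.
#' @return The relaxed `bond_state` (`$converged`, `$iterations`, `$delta`).
#' @export
relax_bonds <- function(state, max_iter = 10000, tol = 1e-10,
                        kb = 0.1, ku = 1, eta = 0.4, shuttle_frac = 0.45,
                        draw = 0.25, record_conservation = FALSE) {
  seg <- state$seg
  n <- nrow(seg)
  int <- !is.na(seg$cell_b)
  L <- seg$length
  Lint <- L[int]

  # long-form ownership index: every (segment, side) with a real cell
  own_long <- c(seg$cell_a, seg$cell_b[int])
  L_long <- c(L, Lint)
  cells_u <- sort(unique(own_long))
  gid <- match(own_long, cells_u)
  Ltot <- as.vector(rowsum(L_long, gid))
  iB <- which(int)

  fda <- seg$free_ds_a; fdb <- seg$free_ds_b
  ffa <- seg$free_ft_a; ffb <- seg$free_ft_b
  bab <- seg$bond_ab; bba <- seg$bond_ba
  sig <- shuttle_frac
  trace <- if (record_conservation) numeric(0) else NULL

  shuttle <- function(fa, fb, wa, wb) {
    # fa/fb: own free densities by side; wa/wb: facing free partner density.
    # The attraction weight is membrane length times (1 + draw * facing free
    # partner density): redistribution is uniform over the membrane at
    # draw = 0 and biased towards segments presenting more unbound partner
    # otherwise, so a pool's presented density stays of the order
    # pool/perimeter instead of collapsing onto the single best segment.
    amt <- c(fa * L, fb[iB] * Lint)
    w <- L_long * (1 + draw * c(wa, wb[iB]))
    Tc <- as.vector(rowsum(amt, gid))
    Wc <- as.vector(rowsum(w, gid))
    wn <- w / Wc[gid]
    new_amt <- (1 - sig) * amt + sig * Tc[gid] * wn
    fa_new <- new_amt[1:n] / L
    fb_new <- fb
    fb_new[iB] <- new_amt[(n + 1):(n + length(iB))] / Lint
    list(a = fa_new, b = fb_new)
  }

  iter <- 0L; delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    # --- binding step (interior segments only) ---
    d1 <- eta * (kb * fda[int] * ffb[int] - ku * bab[int])
    cap1 <- 0.5 * pmin(fda[int], ffb[int])
    d1 <- pmax(pmin(d1, cap1), -bab[int])
    bab[int] <- bab[int] + d1
    fda[int] <- fda[int] - d1
    ffb[int] <- ffb[int] - d1

    d2 <- eta * (kb * fdb[int] * ffa[int] - ku * bba[int])
    cap2 <- 0.5 * pmin(fdb[int], ffa[int])
    d2 <- pmax(pmin(d2, cap2), -bba[int])
    bba[int] <- bba[int] + d2
    fdb[int] <- fdb[int] - d2
    ffa[int] <- ffa[int] - d2

    # --- shuttle step: Ds drawn to facing free Ft, Ft to facing free Ds ---
    sd <- shuttle(fda, fdb, ffb, ffa)
    sf <- shuttle(ffa, ffb, fdb, fda)
    fda <- sd$a; fdb <- sd$b; ffa <- sf$a; ffb <- sf$b

    delta <- max(if (length(d1)) max(abs(d1)) else 0,
                 if (length(d2)) max(abs(d2)) else 0)
    if (record_conservation) {
      tmp <- state
      tmp$seg$free_ds_a <- fda; tmp$seg$free_ds_b <- fdb
      tmp$seg$free_ft_a <- ffa; tmp$seg$free_ft_b <- ffb
      tmp$seg$bond_ab <- bab; tmp$seg$bond_ba <- bba
      trace <- c(trace, bond_conservation(tmp))
    }
    if (delta < tol) break
  }

  state$seg$free_ds_a <- fda; state$seg$free_ds_b <- fdb
  state$seg$free_ft_a <- ffa; state$seg$free_ft_b <- ffb
  state$seg$bond_ab <- bab; state$seg$bond_ba <- bba
  state$iterations <- iter
  state$delta <- delta
  state$converged <- delta < tol
  state$options <- list(max_iter = max_iter, tol = tol, kb = kb, ku = ku,
                        eta = eta, shuttle_frac = shuttle_frac)
  if (record_conservation) state$conservation_trace <- trace
  if (!state$converged)
    warning(sprintf("bond relaxation did not reach tol=%g in %d iterations (delta=%g)",
                    tol, max_iter, delta))
  state
}

#' Maximum protein-conservation error of a bond state
#'
#' For every cell, own free protein plus own protein in bridges must equal
#' the cell's pool.  Returns the largest absolute deviation (in pool units).
#'
#' @param state A `bond_state`.
#' @return Maximum absolute conservation error across cells and proteins.
#' @export
bond_conservation <- function(state) {
  seg <- state$seg
  int <- !is.na(seg$cell_b)
  err <- 0
  for (k in seq_len(nrow(state$pools))) {
    id <- state$pools$id[k]
    ra <- seg$cell_a == id
    rb <- int & seg$cell_b == id
    ds_tot <- sum(seg$free_ds_a[ra] * seg$length[ra]) +
      sum(seg$free_ds_b[rb] * seg$length[rb]) +
      sum(seg$bond_ab[ra] * seg$length[ra]) +
      sum(seg$bond_ba[rb] * seg$length[rb])
    ft_tot <- sum(seg$free_ft_a[ra] * seg$length[ra]) +
      sum(seg$free_ft_b[rb] * seg$length[rb]) +
      sum(seg$bond_ba[ra] * seg$length[ra]) +
      sum(seg$bond_ab[rb] * seg$length[rb])
    err <- max(err, abs(ds_tot - state$pools$pool_ds[k]),
               abs(ft_tot - state$pools$pool_ft[k]))
  }
  err
}

#' Per-segment bridge composition of one cell
#'
#' Tabulates, for every membrane segment of a cell, the density of bridges
#' anchored by the cell's own Ds and own Ft, and tags each segment
#' Ds-majority, Ft-majority or balanced -- the colouring logic of the
#' bridge-disposition cartoon.
#'
#' @param state A relaxed `bond_state`.
#' @param cell Cell id.
#' @param balanced_tol Relative imbalance `|ds - ft| / (ds + ft)` at or below
#'   which a segment is tagged `balanced`.
#' @return A data.frame with one row per segment of the cell.
#' @export
bond_summary <- function(state, cell, balanced_tol = 0.3) {
  seg <- state$seg
  if (!cell %in% state$pools$id)
    stop(sprintf("unknown cell id: %s", cell), call. = FALSE)
  ra <- which(seg$cell_a == cell)
  rb <- which(!is.na(seg$cell_b) & seg$cell_b == cell)
  out <- rbind(
    data.frame(seg = seg$seg[ra], faces = seg$a_faces[ra], axis = seg$axis[ra],
               neighbour = seg$cell_b[ra], length = seg$length[ra],
               own_ds = seg$bond_ab[ra], own_ft = seg$bond_ba[ra]),
    data.frame(seg = seg$seg[rb], faces = seg$b_faces[rb], axis = seg$axis[rb],
               neighbour = seg$cell_a[rb], length = seg$length[rb],
               own_ds = seg$bond_ba[rb], own_ft = seg$bond_ab[rb])
  )
  out$neighbour_row <- ifelse(is.na(out$neighbour), NA_character_,
                              row_of(state$map, out$neighbour))
  tot <- out$own_ds + out$own_ft
  imb <- ifelse(tot > 1e-300, abs(out$own_ds - out$own_ft) / tot, 0)
  out$majority <- ifelse(imb <= balanced_tol, "balanced",
                         ifelse(out$own_ds > out$own_ft, "Ds", "Ft"))
  out[order(out$seg), ]
}
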
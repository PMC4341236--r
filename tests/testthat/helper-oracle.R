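# Independent brute-force reference for the bond relaxation: plain scalar
# loops over an explicit segment list, no shared code with relax_bonds().

oracle_relax <- function(map, activities, kb = 0.1, ku = 1, eta = 0.4,
                         sig = 0.45, draw = 0.25, tol = 1e-12,
                         max_iter = 50000) {
  seg <- map$segments
  n <- nrow(seg)
  act <- activities
  loc <- function(id, faces, which) {
    i <- which(act$id == id)
    a <- act[[paste0(which, "_act_ant")]][i]
    p <- act[[paste0(which, "_act_post")]][i]
    if (faces == "anterior") a else if (faces == "posterior") p else (a + p) / 2
  }
  ids <- act$id
  # pools and initial allocation
  free <- list(ds = matrix(0, n, 2), ft = matrix(0, n, 2))
  pools <- list(ds = numeric(length(ids)), ft = numeric(length(ids)))
  for (k in seq_along(ids)) {
    id <- ids[k]
    per <- 0
    for (r in seq_len(n)) {
      if (seg$cell_a[r] == id) per <- per + seg$length[r]
      if (!is.na(seg$cell_b[r]) && seg$cell_b[r] == id) per <- per + seg$length[r]
    }
    for (w in c("ds", "ft")) {
      i <- which(act$id == id)
      pool <- (act[[paste0(w, "_act_ant")]][i] + act[[paste0(w, "_act_post")]][i]) / 2 * per
      pools[[w]][k] <- pool
      tot <- 0
      for (r in seq_len(n)) {
        if (seg$cell_a[r] == id) tot <- tot + seg$length[r] * loc(id, seg$a_faces[r], w)
        if (!is.na(seg$cell_b[r]) && seg$cell_b[r] == id)
          tot <- tot + seg$length[r] * loc(id, seg$b_faces[r], w)
      }
      if (tot > 0) for (r in seq_len(n)) {
        if (seg$cell_a[r] == id) free[[w]][r, 1] <- pool * loc(id, seg$a_faces[r], w) / tot
        if (!is.na(seg$cell_b[r]) && seg$cell_b[r] == id)
          free[[w]][r, 2] <- pool * loc(id, seg$b_faces[r], w) / tot
      }
    }
  }
  bond_ab <- numeric(n); bond_ba <- numeric(n)

  shuttle_one <- function(fmat, wmat) {
    out <- fmat
    for (k in seq_along(ids)) {
      id <- ids[k]
      rows <- list()
      for (r in seq_len(n)) {
        if (seg$cell_a[r] == id) rows[[length(rows) + 1]] <- c(r, 1)
        if (!is.na(seg$cell_b[r]) && seg$cell_b[r] == id) rows[[length(rows) + 1]] <- c(r, 2)
      }
      tot_amt <- 0; wsum <- 0
      ws <- numeric(length(rows))
      for (j in seq_along(rows)) {
        r <- rows[[j]][1]; s <- rows[[j]][2]
        tot_amt <- tot_amt + fmat[r, s] * seg$length[r]
        ws[j] <- seg$length[r] * (1 + draw * wmat[r, 3 - s])
        wsum <- wsum + ws[j]
      }
      for (j in seq_along(rows)) {
        r <- rows[[j]][1]; s <- rows[[j]][2]
        amt <- (1 - sig) * fmat[r, s] * seg$length[r] + sig * tot_amt * ws[j] / wsum
        out[r, s] <- amt / seg$length[r]
      }
    }
    out
  }

  for (it in seq_len(max_iter)) {
    delta <- 0
    for (r in seq_len(n)) {
      if (is.na(seg$cell_b[r])) next
      d1 <- eta * (kb * free$ds[r, 1] * free$ft[r, 2] - ku * bond_ab[r])
      if (d1 > 0) d1 <- min(d1, 0.5 * min(free$ds[r, 1], free$ft[r, 2]))
      d1 <- max(d1, -bond_ab[r])
      bond_ab[r] <- bond_ab[r] + d1
      free$ds[r, 1] <- free$ds[r, 1] - d1
      free$ft[r, 2] <- free$ft[r, 2] - d1
      d2 <- eta * (kb * free$ds[r, 2] * free$ft[r, 1] - ku * bond_ba[r])
      if (d2 > 0) d2 <- min(d2, 0.5 * min(free$ds[r, 2], free$ft[r, 1]))
      d2 <- max(d2, -bond_ba[r])
      bond_ba[r] <- bond_ba[r] + d2
      free$ds[r, 2] <- free$ds[r, 2] - d2
      free$ft[r, 1] <- free$ft[r, 1] - d2
      delta <- max(delta, abs(d1), abs(d2))
    }
    new_ds <- shuttle_one(free$ds, free$ft)
    new_ft <- shuttle_one(free$ft, free$ds)
    free$ds <- new_ds; free$ft <- new_ft
    if (delta < tol) break
  }
  list(bond_ab = bond_ab, bond_ba = bond_ba, free = free, iterations = it)
}
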
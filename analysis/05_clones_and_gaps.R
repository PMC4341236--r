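#!/usr/bin/env Rscript
# Perturbation scenarios: a small Ds-overexpressing clone repolarises the
# membrane subdomains of contacting wild-type cells towards itself (while
# row 4 cells, pinned by their low-Ds T2 neighbour, keep pointing
# anteriorly, and the clone cells themselves have no preferred polarity);
# a breach in a tendon row leaves the filler cell between two rows of
# near-equal Ds activity, hence unpolarized with centrally placed denticles.

suppressPackageStartupMessages(library(conduitpcp))
dir.create("results", showWarnings = FALSE)

## -- ectoDs clone ----------------------------------------------------------
run <- run_scenario(scenario_config("ectods_clone", seed = 1))
write_run_result(run, file.path("results", "ectods_clone"))
map <- run$map
cids <- map$cells$id[map$cells$ectods_clone]
cat(sprintf("clone: %d cells (rows %s)\n", length(cids),
            paste(map$cells$row_label[match(cids, map$cells$id)], collapse = ", ")))

seg <- run$bonds$seg
n_toward <- 0; n_abut <- 0
for (i in seq_len(nrow(run$conduits))) {
  if (run$conduits$cell[i] %in% cids) next
  for (side in c("anterior", "posterior")) {
    refs <- if (side == "anterior") run$conduits$ant_refs[[i]] else run$conduits$post_refs[[i]]
    nbrs <- setdiff(unique(c(seg$cell_a[refs$idx], seg$cell_b[refs$idx])),
                    run$conduits$cell[i])
    if (any(nbrs %in% cids)) {
      n_abut <- n_abut + 1
      if (run$conduits$call[i] == side) n_toward <- n_toward + 1
    }
  }
}
cat(sprintf("non-clone conduits abutting the clone: %d, pointing toward it: %d\n",
            n_abut, n_toward))
cat(sprintf("clone cells' classification: %s\n",
            paste(run$cells$class[run$cells$cell %in% cids], collapse = ", ")))
r4 <- run$cells[run$cells$row_label == "4" & !(run$cells$cell %in% cids), ]
cat(sprintf("non-clone row 4 cells anterior: %d / %d\n",
            sum(r4$class == "unipolar_anterior"), nrow(r4)))
stopifnot(n_toward == n_abut, all(r4$class == "unipolar_anterior"))

## -- tendon gaps -----------------------------------------------------------
for (sc in c("t1_gap", "t2_gap")) {
  g <- run_scenario(scenario_config(sc, seed = 1))
  write_run_result(g, file.path("results", sc))
  f <- g$map$cells$id[g$map$cells$is_gap_filler]
  d <- g$denticles[g$denticles$cell == f, ]
  cat(sprintf("\n%s: filler cell %d class = %s; denticles %s, orientations %s\n",
              sc, f, g$cells$class[g$cells$cell == f],
              paste(unique(d$placement), collapse = "/"),
              paste(table(d$orientation), collapse = ":")))
  stopifnot(g$cells$class[g$cells$cell == f] == "unpolarized",
            all(d$placement == "central"))
}
cat("\ngap fillers develop no defined polarity; their denticles sit mid-cell\n")
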
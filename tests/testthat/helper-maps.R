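# Small custom tissues and parameter tables used across tests.

# Single-column strip of cells with arbitrary row labels, built through the
# package's own geometry plumbing.
make_strip_map <- function(labels, cell_size = 30, seg_len = 2) {
  n <- length(labels)
  polygons <- list()
  for (r in seq_len(n)) {
    polygons[[as.character(r)]] <- matrix(
      c((r - 1) * cell_size, 0, r * cell_size, 0,
        r * cell_size, cell_size, (r - 1) * cell_size, cell_size),
      ncol = 2, byrow = TRUE)
  }
  cells <- data.frame(
    id = seq_len(n), row_label = labels, col = 1L,
    is_tendon = labels %in% c("T1", "T2"),
    is_atypical = FALSE, is_gap_filler = FALSE,
    ds_null = FALSE, ft_null = FALSE, ectods_clone = FALSE,
    stringsAsFactors = FALSE)
  map <- structure(list(
    cells = cells, polygons = polygons, cell_size = cell_size,
    seg_len = seg_len, n_columns = 1L, n_segments = 1L, trailing_p = FALSE,
    axis = "x: anterior -> posterior (um); y: mediolateral (um)"),
    class = "cell_map")
  map$segments <- conduitpcp:::build_interfaces(map)
  map
}

# Expression parameter table from plain per-label vectors (fj = 0 unless
# given), so strip tests can set activities directly.
strip_params <- function(ds, ft = NULL, fj = NULL) {
  labs <- names(ds)
  if (is.null(ft)) ft <- setNames(rep(1, length(labs)), labs)
  if (is.null(fj)) fj <- setNames(rep(0, length(labs)), labs)
  data.frame(row_label = labs, ds_expr = unname(ds[labs]),
             ft_expr = unname(ft[labs]), fj_expr = unname(fj[labs]),
             stringsAsFactors = FALSE)
}

relaxed_strip <- function(labels, ds, ft = NULL, fj = NULL, ...) {
  map <- make_strip_map(labels)
  st <- compute_activities(assign_expression(map, strip_params(ds, ft, fj)))
  b <- relax_bonds(initialise_bonds(map, st), ...)
  list(map = map, state = st, bonds = b)
}

# Scenario runs are deterministic and reused across test files.
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(scenario, seed = 1, ...) {
  key <- paste(scenario, seed, ..., sep = "_")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_scenario(scenario_config(scenario, seed = seed, ...))
  .run_cache[[key]]
}

# Cells abutting a given conduit side (helper for clone assertions).
conduit_side_neighbours <- function(run, i, side) {
  refs <- if (side == "anterior") run$conduits$ant_refs[[i]] else run$conduits$post_refs[[i]]
  seg <- run$bonds$seg
  setdiff(unique(c(seg$cell_a[refs$idx], seg$cell_b[refs$idx])),
          run$conduits$cell[i])
}
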
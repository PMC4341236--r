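# ---------------------------------------------------------------------------
# Scenario orchestration: tissue -> activities -> bonds -> conduits ->
# denticles -> statistics, with one resolved, serialisable configuration.
# ---------------------------------------------------------------------------

SCENARIOS <- c("wildtype", "atypical_row2", "atypical_row3", "atypical_row4",
               "t1_gap", "t2_gap", "ds_ft_null", "ectods_clone")

#' Build a resolved scenario configuration
#'
#' Returns the full parameter set of a run; every field can be overridden
#' through `...`.  Scenario presets: `wildtype` (plain lattice),
#' `atypical_row2`/`_row3`/`_row4` (one reshaped two-row cell),
#' `t1_gap`/`t2_gap` (one-cell breach in a tendon row), `ds_ft_null`
#' (bridge-free epidermis carrying several atypical row 4 cells, for the
#' indeterminacy statistics), `ectods_clone` (a small Ds-overexpressing
#' clone seeded in row 3).
#'
#' @param scenario One of the preset names.
#' @param seed Integer seed for all stochastic stages of the run.
#' @param ... Named overrides of any default field.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = "wildtype", seed = 1, ...) {
  scenario <- match.arg(scenario, SCENARIOS)
  cfg <- list(
    scenario = scenario, seed = as.integer(seed),
    n_columns = 5L, n_segments = 1L, cell_size = 30, seg_len = 2,
    trailing_p = TRUE,
    gradient = FALSE, alpha = 1, beta = 1, clone_K = 5,
    max_iter = 10000L, tol = 1e-10, kb = 0.1, ku = 1, eta = 0.4,
    shuttle_frac = 0.45, draw = 0.25,
    band_width = 5, theta = 0.02, theta_frac = 0.02,
    denticles_per_conduit = 1L, membrane_offset = 1.5,
    force_clone_unpolarized = TRUE,
    atypical_cols = NULL, atypical_row = NULL,
    promontory_height = 10, promontory_depth = NULL,
    gap_row = NULL, gap_col = NULL, gap_width = 1L,
    clone_size = 2L, clone_start_row = "3",
    all_ds_ft_null = FALSE
  )
  if (scenario %in% c("atypical_row2", "atypical_row3", "atypical_row4")) {
    cfg$atypical_row <- sub("atypical_row", "", scenario)
    cfg$atypical_cols <- 2L
  } else if (scenario == "t1_gap") {
    cfg$gap_row <- "T1"
  } else if (scenario == "t2_gap") {
    cfg$gap_row <- "T2"
  } else if (scenario == "ds_ft_null") {
    cfg$all_ds_ft_null <- TRUE
    cfg$n_columns <- 7L
    cfg$atypical_row <- "4"
    cfg$atypical_cols <- c(1L, 3L, 5L)
    cfg$denticles_per_conduit <- 3L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    config_error(paste(unknown, collapse = ", "), "is not a scenario field")
  cfg[names(over)] <- over
  class(cfg) <- "scenario_config"
  cfg
}

build_scenario_map <- function(cfg) {
  map <- build_segment_map(n_columns = cfg$n_columns,
                           n_segments = cfg$n_segments,
                           cell_size = cfg$cell_size, seg_len = cfg$seg_len,
                           trailing_p = cfg$trailing_p)
  if (!is.null(cfg$atypical_row)) {
    for (cc in cfg$atypical_cols) {
      map <- insert_atypical_cell(map, cfg$atypical_row, col = cc,
                                  promontory_height = cfg$promontory_height,
                                  promontory_depth = cfg$promontory_depth)
    }
  }
  if (!is.null(cfg$gap_row)) {
    map <- insert_tendon_gap(map, cfg$gap_row, col = cfg$gap_col,
                             width = cfg$gap_width)
  }
  if (cfg$all_ds_ft_null) {
    map$cells$ds_null <- TRUE
    map$cells$ft_null <- TRUE
  }
  if (cfg$scenario == "ectods_clone") {
    start <- find_cell(map, cfg$clone_start_row,
                       max(1L, floor(map$n_columns / 2)))
    map <- mark_clone(map, seed = cfg$seed, size = cfg$clone_size,
                      start = start)
  }
  map
}

#' Run a scenario end to end
#'
#' Executes every stage in order -- synthetic tissue, expression and
#' activities, genotype perturbation, bond relaxation, conduit scoring,
#' cell classification, denticle placement, and (for the atypical and
#' mutant scenarios) the contingency statistics.
#'
#' @param config A `scenario_config`.
#' @param verbose Log stage progress to stderr.
#' @return A `run_result` list: `map`, `activities`, `bonds`, `conduits`,
#'   `cells`, `denticles`, `tables`, `summary`, `config`.
#' @export
run_scenario <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  say("[%s] building tissue", config$scenario)
  map <- build_scenario_map(config)

  say("[%s] expression and activities", config$scenario)
  st <- assign_expression(map, gradient = config$gradient)
  st <- compute_activities(st, alpha = config$alpha, beta = config$beta)
  st <- apply_genotype(st, map, K = config$clone_K)

  say("[%s] relaxing bonds", config$scenario)
  bonds <- initialise_bonds(map, st)
  bonds <- relax_bonds(bonds, max_iter = config$max_iter, tol = config$tol,
                       kb = config$kb, ku = config$ku, eta = config$eta,
                       shuttle_frac = config$shuttle_frac, draw = config$draw)
  say("[%s] relaxed in %d iterations (delta=%g)", config$scenario,
      bonds$iterations, bonds$delta)

  conduits <- build_conduits(map, bonds, band_width = config$band_width)
  conduits <- score_conduits(conduits, bonds, theta = config$theta,
                             theta_frac = config$theta_frac)
  cells <- classify_cells(conduits, map,
                          force_clone_unpolarized = config$force_clone_unpolarized)
  if (config$force_clone_unpolarized) {
    forced <- cells$cell[cells$forced | (cells$class == "unpolarized" &
      map$cells$ectods_clone[match(cells$cell, map$cells$id)])]
    conduits$call[conduits$cell %in% forced] <- "unpolarized"
  }

  dent <- with_local_seed(config$seed,
    place_denticles(map, conduits, count = config$denticles_per_conduit,
                    membrane_offset = config$membrane_offset))

  tables <- list()
  if (!is.null(config$atypical_row)) {
    side <- if (config$atypical_row == "2") "anterior" else "posterior"
    atyp <- map$cells$id[map$cells$is_atypical]
    sub <- dent[dent$cell %in% atyp, , drop = FALSE]
    if (nrow(sub) > 0) {
      sub <- classify_denticle_domain(sub, map, side = side)
      ct <- build_table(sub, allocation_mode = "none")
      tables[[paste0("atypical_row", config$atypical_row)]] <- list(
        table = ct, side = side, p_value = fisher_exact(ct))
    }
  }

  summary <- list(
    scenario = config$scenario, seed = config$seed,
    n_cells = nrow(map$cells), n_segments = nrow(map$segments),
    n_conduits = nrow(conduits), n_denticles = nrow(dent),
    relax_iterations = bonds$iterations, relax_delta = bonds$delta,
    converged = bonds$converged,
    theta = if (nrow(conduits)) conduits$theta[1] else NA,
    class_counts = as.list(table(cells$class)),
    p_values = lapply(tables, function(t) t$p_value),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  structure(list(map = map, activities = st, bonds = bonds,
                 conduits = conduits, cells = cells, denticles = dent,
                 tables = tables, summary = summary, config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<run_result> %s (seed %d): %d cells, %d conduits, %d denticles\n",
              s$scenario, s$seed, s$n_cells, s$n_conduits, s$n_denticles))
  cat("  classes:", paste(names(s$class_counts), unlist(s$class_counts),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Persist a run result as text files
#'
#' Writes `map.json`, `denticles.tsv`, `conduits.tsv`, `tables.tsv`,
#' `summary.json` and `tissue.svg` into `dir`.  Outputs are byte-identical
#' for identical config and seed.
#'
#' @param result A `run_result`.
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_run_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_map(result$map, file.path(dir, "map.json"))

  cond <- result$conduits
  cond_out <- data.frame(conduit = cond$conduit, cell = cond$cell,
                         band = cond$band, y0 = cond$y0, y1 = cond$y1,
                         ant_labels = cond$ant_labels,
                         post_labels = cond$post_labels,
                         score = cond$score, call = cond$call)
  write_stats_tsv(cond_out, file.path(dir, "conduits.tsv"))
  write_stats_tsv(result$denticles, file.path(dir, "denticles.tsv"))

  tab_rows <- list()
  for (nm in names(result$tables)) {
    t <- result$tables[[nm]]
    m <- t$table$table
    tab_rows[[nm]] <- data.frame(
      scenario = result$config$scenario, table = nm, side = t$side,
      a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
      p_value = t$p_value, allocation_mode = t$table$allocation_mode)
  }
  if (length(tab_rows)) {
    write_stats_tsv(do.call(rbind, tab_rows), file.path(dir, "tables.tsv"))
  }
  cfg <- result$config; class(cfg) <- NULL
  summ <- result$summary
  summ$elapsed_s <- NULL  # wall time is not part of the reproducible output
  jsonlite::write_json(list(summary = summ, config = cfg),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  render_map(result, file.path(dir, "tissue.svg"))
  invisible(dir)
}
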
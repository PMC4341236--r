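#!/usr/bin/env Rscript
# Atypical cells span two rows, so different membrane subdomains face
# neighbours of different type.  The conduit comparison then predicts: an
# atypical row 4 cell is multipolar (the T2-abutting subdomain points
# anteriorly, the row-4-abutting one posteriorly), while atypical row 2 and
# row 3 cells stay unipolar-posterior.  This reproduces the sign structure
# of the published wild-type contingency tables deterministically.

suppressPackageStartupMessages(library(conduitpcp))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (sc in c("atypical_row2", "atypical_row3", "atypical_row4")) {
  run <- run_scenario(scenario_config(sc, seed = 1))
  write_run_result(run, file.path("results", sc))
  at <- run$map$cells$id[run$map$cells$is_atypical]
  cat(sprintf("\n== %s: atypical cell %d -> %s\n", sc, at,
              run$cells$class[run$cells$cell == at]))
  ca <- run$conduits[run$conduits$cell == at, ]
  print(unique(ca[, c("ant_labels", "post_labels", "call")]), row.names = FALSE)
  if (length(run$tables)) {
    t <- run$tables[[1]]
    cat(sprintf("2x2 (side = %s), Fisher p = %.4g:\n", t$side, t$p_value))
    print(t$table$table)
    m <- t$table$table
    rows[[sc]] <- data.frame(scenario = sc, side = t$side,
                             a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
                             p_value = t$p_value)
  }
}
write_stats_tsv(do.call(rbind, rows), file.path("results", "atypical_tables.tsv"))
cat("\nIn the wild-type model the off-pattern cells of each table are zero:\n")
cat("every tendon-abutting subdomain points anteriorly (row 4) and all\n")
cat("atypical row 2 denticles point posteriorly, as in the published counts\n")
cat("once their ambiguous-predenticle allocations are removed.\n")
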
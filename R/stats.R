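# ---------------------------------------------------------------------------
# Denticle-polarity quantitation: abutting-domain classification, 2x2
# contingency tables with ambiguous-denticle allocation, and a
# first-principles Fisher exact test (log-space hypergeometric enumeration,
# plus an exact rational-arithmetic variant used as an independent check).
# ---------------------------------------------------------------------------

#' Classify denticles by the neighbour type their domain abuts
#'
#' Following the scoring protocol for atypical cells, each denticle is
#' classed by the cell its membrane subdomain abuts on the analysis side:
#' `tendon` (T1 or T2), `non_tendon` (another denticulate cell), or
#' `intermediate` when the subdomain abuts neighbours of mixed type or no
#' cell at all.  For atypical row 4 cells the informative side is posterior
#' (T2 vs row 4); for atypical row 2 cells it is anterior (T1 vs row 2).
#'
#' @param denticles Denticle table from [place_denticles()].
#' @param map The `cell_map`.
#' @param side `"posterior"` or `"anterior"`: which membrane's neighbour
#'   classifies the domain.
#' @return The denticle table with a `domain_class` column.
#' @export
classify_denticle_domain <- function(denticles, map,
                                     side = c("posterior", "anterior")) {
  side <- match.arg(side)
  labs <- if (side == "posterior") denticles$post_labels else denticles$ant_labels
  cls <- vapply(labs, function(s) {
    if (is.na(s) || !nzchar(s)) return("intermediate")
    parts <- strsplit(s, "+", fixed = TRUE)[[1]]
    tn <- parts %in% TENDON_ROWS
    if (all(tn)) "tendon" else if (all(!tn)) "non_tendon" else "intermediate"
  }, character(1), USE.NAMES = FALSE)
  denticles$domain_class <- cls
  denticles
}

#' Build a 2x2 denticle-polarity contingency table
#'
#' Rows are the abutting-domain class (tendon vs non-tendon), columns the
#' denticle orientation (anteriorly vs posteriorly).  Denticles in
#' intermediate domains are allocated one at a time to the class that makes
#' the association weakest (`favour_null`), strongest (`disfavour_null`), or
#' are dropped (`none`), the allocation being decided by the resulting
#' Fisher exact p-value -- the convention used for scoring ambiguous
#' predenticles.
#'
#' @param denticles Classified denticle table
#'   (see [classify_denticle_domain()]).
#' @param allocation_mode `"favour_null"`, `"disfavour_null"` or `"none"`.
#' @return A `contingency_2x2` object: `$table` (2x2 integer matrix),
#'   `$n_intermediate`, `$allocation_mode`.
#' @export
build_table <- function(denticles,
                        allocation_mode = c("none", "favour_null",
                                            "disfavour_null")) {
  allocation_mode <- match.arg(allocation_mode)
  if (nrow(denticles) == 0) stop("empty table: no denticles", call. = FALSE)
  if (!"domain_class" %in% names(denticles))
    stop("denticles must be classified first (classify_denticle_domain)",
         call. = FALSE)
  tab <- matrix(0L, 2, 2,
                dimnames = list(domain = c("tendon", "non_tendon"),
                                orientation = c("anteriorly", "posteriorly")))
  for (i in which(denticles$domain_class != "intermediate")) {
    r <- denticles$domain_class[i]
    cc <- if (denticles$orientation[i] == "anterior") 1L else 2L
    tab[r, cc] <- tab[r, cc] + 1L
  }
  inter <- which(denticles$domain_class == "intermediate")
  if (allocation_mode != "none") {
    for (i in inter) {
      cc <- if (denticles$orientation[i] == "anterior") 1L else 2L
      p <- numeric(2)
      for (r in 1:2) {
        t2 <- tab; t2[r, cc] <- t2[r, cc] + 1L
        p[r] <- fisher_exact(t2)
      }
      r <- if (allocation_mode == "favour_null") which.max(p) else which.min(p)
      tab[r, cc] <- tab[r, cc] + 1L
    }
  }
  structure(list(table = tab, n_intermediate = length(inter),
                 allocation_mode = allocation_mode),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2> allocation:", x$allocation_mode,
      sprintf("(%d intermediate)\n", x$n_intermediate))
  print(x$table)
  invisible(x)
}

as_table_matrix <- function(table) {
  if (inherits(table, "contingency_2x2")) table <- table$table
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("validation error: negative counts", call. = FALSE)
  if (any(table != round(table))) stop("counts must be integers", call. = FALSE)
  storage.mode(table) <- "double"
  table
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins under the hypergeometric
#' distribution and sums the point probabilities not exceeding the observed
#' table's (with relative tie tolerance 1e-7) -- the point-probability
#' two-sided convention.  Probabilities are computed with log-space
#' factorials.  Degenerate margins give p = 1.
#'
#' @param table 2x2 matrix of counts or a `contingency_2x2`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table) {
  m <- as_table_matrix(table)
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]; c2 <- m[1, 2] + m[2, 2]
  n <- r1 + r2
  if (n == 0) stop("empty table: total count is zero", call. = FALSE)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  a <- lo:hi
  logp <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  lobs <- logp[a == m[1, 1]]
  p <- sum(exp(logp[logp <= lobs + log(1 + 1e-7)]))
  min(1, p)
}

# --- exact rational arithmetic (independent oracle path) -------------------
#
# Point probabilities share the denominator choose(n, c1), and the
# numerators choose(r1, a) * choose(r2, c1 - a) are exact integers.  They
# are built from the prime factorisation of factorials (Legendre's formula)
# on a tiny base-1e4 big-integer type, so enumeration, comparison and
# summation are exact; only the final division is done in floating point.

big_from_int <- function(x) {
  v <- integer(0)
  while (x > 0) { v <- c(v, x %% 10000L); x <- x %/% 10000L }
  if (length(v) == 0) v <- 0L
  v
}

big_mul_small <- function(b, s) {
  carry <- 0; out <- integer(0)
  for (d in b) {
    t <- d * s + carry
    out <- c(out, t %% 10000)
    carry <- t %/% 10000
  }
  while (carry > 0) { out <- c(out, carry %% 10000); carry <- carry %/% 10000 }
  as.integer(out)
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a))); b <- c(b, integer(n - length(b)))
  s <- a + b; carry <- 0L
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 10000L
    s[i] <- s[i] %% 10000L
  }
  if (carry > 0) s <- c(s, carry)
  s
}

big_cmp <- function(a, b) {
  while (length(a) > 1 && a[length(a)] == 0L) a <- a[-length(a)]
  while (length(b) > 1 && b[length(b)] == 0L) b <- b[-length(b)]
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) if (a[i] != b[i]) return(sign(a[i] - b[i]))
  0
}

big_to_double <- function(b) sum(as.numeric(b) * 10000^(seq_along(b) - 1))

# exponent of prime p in n! (Legendre)
legendre_exp <- function(n, p) {
  e <- 0; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

primes_upto <- function(n) {
  if (n < 2) return(integer(0))
  s <- rep(TRUE, n); s[1] <- FALSE
  i <- 2
  while (i * i <= n) {
    if (s[i]) s[seq(i * i, n, by = i)] <- FALSE
    i <- i + 1
  }
  which(s)
}

#' Fisher exact test by exact rational enumeration
#'
#' Independent implementation of [fisher_exact()] for totals up to a few
#' hundred, using exact integer arithmetic throughout: hypergeometric point
#' probabilities are represented by their integer numerators over the common
#' denominator `choose(n, c1)`, built from prime factorisations, so the
#' extreme-table comparison and the summation are exact.
#'
#' @param table 2x2 matrix of counts or a `contingency_2x2`.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_rational <- function(table) {
  m <- as_table_matrix(table)
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]; c2 <- m[1, 2] + m[2, 2]
  n <- r1 + r2
  if (n == 0) stop("empty table: total count is zero", call. = FALSE)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  pr <- primes_upto(n)
  fexp <- function(k) vapply(pr, function(p) legendre_exp(k, p), numeric(1))
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  nums <- list()
  for (a in lo:hi) {
    b <- c1 - a
    e <- fexp(r1) - fexp(a) - fexp(r1 - a) + fexp(r2) - fexp(b) - fexp(r2 - b)
    big <- 1L
    for (i in seq_along(pr)) {
      if (e[i] > 0) for (j in seq_len(e[i])) big <- big_mul_small(big, pr[i])
    }
    nums[[as.character(a)]] <- big
  }
  obs <- nums[[as.character(m[1, 1])]]
  psum <- 0L; tot <- 0L
  for (a in lo:hi) {
    v <- nums[[as.character(a)]]
    tot <- big_add(tot, v)
    if (big_cmp(v, obs) <= 0) psum <- big_add(psum, v)
  }
  big_to_double(psum) / big_to_double(tot)
}

# --- published contingency tables fixture ----------------------------------

#' Load the published atypical-cell contingency tables
#'
#' Returns the four published 2x2 tables of denticle polarity versus
#' abutting-neighbour type for atypical row 2 and row 4 cells, in wild type
#' and in the `ds- ft-` mutant, with their footnote metadata (number of
#' cells scored, ambiguous-denticle allocation, printed p-values).
#'
#' @return A named list of entries with `$table` (2x2 matrix), `$genotype`,
#'   `$row_class`, `$n_cells`, `$allocation`, `$printed_p`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.json", package = "conduitpcp")
  if (!nzchar(path)) stop("table1.json fixture not found", call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(doc$tables, function(t) {
    m <- matrix(unlist(t$counts), 2, 2, byrow = TRUE,
                dimnames = list(domain = unlist(t$row_names),
                                orientation = unlist(t$col_names)))
    list(table = m, genotype = t$genotype, row_class = t$row_class,
         n_cells = t$n_cells, allocation = t$allocation,
         printed_p = if (is.null(t$printed_p)) NA else t$printed_p,
         p_is_upper_bound = isTRUE(t$p_is_upper_bound),
         note = t$note)
  })
  names(out) <- vapply(doc$tables, function(t) t$name, character(1))
  out
}

#' Write a contingency-statistics TSV
#'
#' @param rows A data.frame with columns scenario, genotype, row_class,
#'   a, b, c, d, p_value, allocation_mode.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_stats_tsv <- function(rows, path) {
  num <- vapply(rows, is.numeric, logical(1))
  for (cn in names(rows)[num]) rows[[cn]] <- format_num(rows[[cn]])
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15, sprintf("%.0f", x),
                sprintf("%.10g", x)))
}
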
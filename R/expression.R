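# ---------------------------------------------------------------------------
# Ds / Ft / Fj expression and the derived activity landscape.
#
# The model carries, per cell, expression levels of dachsous (ds), fat (ft)
# and four-jointed (fj) in arbitrary units, and the Fj-modulated *activities*
# that actually drive heterodimer formation.  Fj phosphorylates both
# protocadherins, activating Ft and deactivating Ds, so
#   ds_act = ds_expr / (1 + alpha * fj_expr)
#   ft_act = ft_expr * (1 + beta  * fj_expr)
# Activities are evaluated at the anterior and posterior limits of each cell
# (the within-cell gradient) by interpolating the row profile midway to the
# abutting neighbours.
# ---------------------------------------------------------------------------

#' Default per-row expression parameters
#'
#' Returns the wild-type expression table.  The literature constrains only
#' orderings: tendon rows have by far the highest `fj` and the lowest Ds
#' activity; `fj` is graded from row 2 (high) to row 4 (low); Ds activity in
#' row 3 lies between T2 and row 4; rows 1 and 3, and rows 4 and 6, carry
#' near-identical Ds activity (this is what renders tendon-gap filler cells
#' directionless).  The numbers here are arbitrary units chosen once to
#' satisfy all of those constraints; with the default `alpha = beta = 1`
#' the resulting Ds activities are P 0.7, row0 0.8, row1 0.6, T1 0.1,
#' row2 0.45, row3 0.6, row4 0.8, T2 0.1, row5 0.6, row6 0.8.  The `fj`
#' values of the rows the literature leaves unconstrained (P, row 0) are set
#' so that the tissue is near mirror-symmetric about each tendon row out to
#' second neighbours, which is what leaves a tendon-gap filler cell without
#' a directional cue.
#'
#' @return A data.frame with columns `row_label`, `ds_expr`, `ft_expr`,
#'   `fj_expr`.
#' @export
default_expression_params <- function() {
  fj <- c(P = 0.2, `0` = 0.1, `1` = 0.3, T1 = 1.0, `2` = 0.6,
          `3` = 0.3, `4` = 0.1, T2 = 1.0, `5` = 0.05, `6` = 0.1)
  ds_act <- c(P = 0.7, `0` = 0.8, `1` = 0.6, T1 = 0.1, `2` = 0.45,
              `3` = 0.6, `4` = 0.8, T2 = 0.1, `5` = 0.6, `6` = 0.8)
  data.frame(
    row_label = names(fj),
    ds_expr = unname(ds_act * (1 + fj)),
    ft_expr = 1.0,
    fj_expr = unname(fj),
    stringsAsFactors = FALSE
  )
}

#' Assign Ds/Ft/Fj expression to every cell of a map
#'
#' Looks up each cell's row in the parameter table and sets per-cell
#' expression.  With `gradient = TRUE`, anterior/posterior endpoint
#' expression is additionally sloped by linear interpolation towards the
#' abutting rows (the within-cell gradient of the transect cartoons); the
#' default is a uniform within-cell profile, which keeps the comparison a
#' cell makes a pure function of its neighbours' row identities.
#'
#' @param map A `cell_map`.
#' @param params Per-row table as from [default_expression_params()]; must
#'   cover every row label present in the map.
#' @param gradient Interpolate endpoint expression towards neighbours.
#' @return An `activity_state` data.frame (one row per cell).
#' @export
assign_expression <- function(map, params = default_expression_params(),
                              gradient = FALSE) {
  labs <- unique(map$cells$row_label)
  missing <- setdiff(labs, params$row_label)
  if (length(missing))
    config_error("params", paste("is missing row label(s):",
                                 paste(missing, collapse = ", ")))
  idx <- match(map$cells$row_label, params$row_label)
  st <- data.frame(
    id = map$cells$id,
    row_label = map$cells$row_label,
    ds_expr = params$ds_expr[idx],
    ft_expr = params$ft_expr[idx],
    fj_expr = params$fj_expr[idx],
    stringsAsFactors = FALSE
  )
  endp <- function(i, side, what) {
    own <- st[[what]][i]
    if (!gradient) return(own)
    nb <- neighbours(map, st$id[i], side = side)
    if (length(nb) == 0) return(own)
    (own + mean(st[[what]][match(nb, st$id)])) / 2
  }
  n <- nrow(st)
  st$ds_expr_ant <- vapply(seq_len(n), endp, numeric(1), side = "anterior", what = "ds_expr")
  st$ds_expr_post <- vapply(seq_len(n), endp, numeric(1), side = "posterior", what = "ds_expr")
  st$ft_expr_ant <- vapply(seq_len(n), endp, numeric(1), side = "anterior", what = "ft_expr")
  st$ft_expr_post <- vapply(seq_len(n), endp, numeric(1), side = "posterior", what = "ft_expr")
  class(st) <- c("activity_state", "data.frame")
  st
}

#' Compute Fj-modulated Ds and Ft activities
#'
#' @param state An `activity_state` from [assign_expression()].
#' @param alpha Strength of Fj's deactivation of Ds (>= 0).
#' @param beta Strength of Fj's activation of Ft (>= 0).
#' @return The state with `ds_act_*` and `ft_act_*` columns; increasing `fj`
#'   never increases `ds_act` nor decreases `ft_act`.
#' @export
compute_activities <- function(state, alpha = 1, beta = 1) {
  if (alpha < 0) config_error("alpha", "must be >= 0")
  if (beta < 0) config_error("beta", "must be >= 0")
  down <- 1 / (1 + alpha * state$fj_expr)
  up <- 1 + beta * state$fj_expr
  state$ds_act_ant <- state$ds_expr_ant * down
  state$ds_act_post <- state$ds_expr_post * down
  state$ft_act_ant <- state$ft_expr_ant * up
  state$ft_act_post <- state$ft_expr_post * up
  state
}

#' Apply genotype perturbations to an activity state
#'
#' `ds_null` / `ft_null` zero the respective contribution ("these bridges
#' cannot form without either or both of these proteins"); `ectods_clone`
#' multiplies Ds activity by `K`, chosen so that clone cells exceed every
#' non-clone cell's Ds activity by a wide margin.
#'
#' @param state An `activity_state` with computed activities.
#' @param map The `cell_map` carrying genotype flags.
#' @param K Overexpression factor for `ectods_clone` cells.
#' @return The perturbed state.
#' @export
apply_genotype <- function(state, map, K = 20) {
  idx <- match(state$id, map$cells$id)
  dsn <- map$cells$ds_null[idx]
  ftn <- map$cells$ft_null[idx]
  cl <- map$cells$ectods_clone[idx]
  for (cn in c("ds_expr", "ds_expr_ant", "ds_expr_post",
               "ds_act_ant", "ds_act_post"))
    if (cn %in% names(state)) state[[cn]][dsn] <- 0
  for (cn in c("ft_expr", "ft_expr_ant", "ft_expr_post",
               "ft_act_ant", "ft_act_post"))
    if (cn %in% names(state)) state[[cn]][ftn] <- 0
  if (any(cl) && all(c("ds_act_ant", "ds_act_post") %in% names(state))) {
    state$ds_act_ant[cl] <- state$ds_act_ant[cl] * K
    state$ds_act_post[cl] <- state$ds_act_post[cl] * K
  }
  state
}

#' Audit the wild-type Ds-activity ordering
#'
#' Asserts the orderings the polarity pattern relies on: tendon rows are the
#' strict minima of Ds activity; T2 < row 3 < row 4; row 2 < row 4; fj is
#' maximal in tendons and graded row 2 > row 3 > row 4.
#'
#' @param state An `activity_state` with computed activities.
#' @return `TRUE` invisibly; errors on violation.
#' @export
audit_activity_ordering <- function(state) {
  act <- function(lab) {
    r <- state$row_label == lab
    if (!any(r)) return(NA_real_)
    mean((state$ds_act_ant[r] + state$ds_act_post[r]) / 2)
  }
  fj <- function(lab) {
    r <- state$row_label == lab
    if (!any(r)) return(NA_real_)
    mean(state$fj_expr[r])
  }
  tend <- c(act("T1"), act("T2"))
  others <- vapply(c("P", DENTICLE_ROWS), act, numeric(1))
  others <- others[!is.na(others)]
  stopifnot(
    "tendon Ds activity must be the strict minimum" =
      max(tend, na.rm = TRUE) < min(others),
    "need T2 < row3 < row4 Ds activity" =
      act("T2") < act("3") && act("3") < act("4"),
    "need row2 < row4 Ds activity" = act("2") < act("4"),
    "fj must be maximal in tendon cells" =
      min(fj("T1"), fj("T2")) > max(fj("2"), fj("3"), fj("4")),
    "fj must be graded row2 > row3 > row4" =
      fj("2") > fj("3") && fj("3") > fj("4")
  )
  invisible(TRUE)
}
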
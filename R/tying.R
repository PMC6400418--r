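#' Declarative parameter tying across design cells
#'
#' A model variant is defined by how the four observer parameters (`p_ego`,
#' `a_max`, `a_scale`, `p_lapse`) are shared across the condition/set-size
#' cells of a dataset. For each parameter, choose a grouping:
#' `"shared"` (one free slot for all cells), `"by_set_size"`,
#' `"by_condition"`, or `"by_cell"` (one slot per cell); or fix the parameter
#' to a constant via `fixed` (e.g. `fixed = list(a_max = 0)` gives the reduced
#' model with no allocentric component). Allocentric parameters are only free
#' in cells whose condition is in `allo_conditions`; in all other cells they
#' are fixed at 0. Fixing `a_max` to 0 also fixes `a_scale` (it is then
#' unidentifiable). An optional `cost` parameter converts the variant into the
#' egocentric-cost model: `p_ego` slots then describe landmark-absent
#' precision and cells in `cost_conditions` use `p_ego * (1 - cost)`.
#'
#' Free slots are numbered contiguously; the slot count is the variant's `k`
#' for AICc.
#'
#' @param cells data frame with columns `condition` and `set_size`, one row
#'   per design cell (see [dataset_cells()]).
#' @param p_ego,a_max,a_scale,p_lapse grouping keywords (see Details).
#' @param fixed named list of parameters to fix (numeric constants).
#' @param allo_conditions conditions with an active allocentric component.
#' @param cost logical; include the cost parameter?
#' @param cost_conditions conditions the cost applies to; `NULL` = every
#'   condition except LM_ABSENT.
#' @param allow_negative_cost logical; widen the cost bound from [0, 1] to
#'   [-1, 1].
#' @param bounds optional named list overriding optimizer box bounds, each a
#'   `c(lower, upper)` pair; defaults: `p_ego` and `a_max` [0, 1e6] (a large
#'   finite stand-in for an unbounded precision), `a_scale` [0, 500],
#'   `p_lapse` [0, 1].
#' @param shift_reference `"pre"` or `"post"` landmark position for LM_SHIFT
#'   distances.
#' @return an object of class `param_tying` with elements `cells`, `slots`
#'   (one row per free slot: parameter, group label, bounds), `assign`
#'   (cell-by-parameter slot indices), `fixed_values`, `k`, and the variant
#'   flags.
#' @examples
#' cells <- data.frame(condition = c("LM_PRESENT", "LM_ABSENT"), set_size = 4)
#' param_tying(cells)                        # full model, k = 4
#' param_tying(cells, fixed = list(a_max = 0))  # reduced model, k = 2
#' @export
param_tying <- function(cells,
                        p_ego = "by_set_size", a_max = "by_set_size",
                        a_scale = "shared", p_lapse = "by_set_size",
                        fixed = list(),
                        allo_conditions = .ALLO_CONDITIONS,
                        cost = FALSE, cost_conditions = NULL,
                        allow_negative_cost = FALSE,
                        bounds = list(),
                        shift_reference = c("pre", "post")) {
  shift_reference <- match.arg(shift_reference)
  stopifnot(is.data.frame(cells), all(c("condition", "set_size") %in%
                                        names(cells)))
  cells <- unique(cells[, c("condition", "set_size")])
  cells <- cells[order(cells$condition, cells$set_size), , drop = FALSE]
  rownames(cells) <- NULL
  if (!all(cells$condition %in% .CONDITIONS))
    stop("unknown condition(s): ",
         paste(setdiff(cells$condition, .CONDITIONS), collapse = ", "))
  nc <- nrow(cells)

  default_bounds <- list(p_ego = c(0, 1e6), a_max = c(0, 1e6),
                         a_scale = c(0, 500), p_lapse = c(0, 1),
                         cost = if (allow_negative_cost) c(-1, 1) else c(0, 1))
  for (nm in names(bounds)) default_bounds[[nm]] <- bounds[[nm]]

  grouping <- list(p_ego = p_ego, a_max = a_max, a_scale = a_scale,
                   p_lapse = p_lapse)
  if ("a_max" %in% names(fixed) && fixed$a_max == 0 &&
      !("a_scale" %in% names(fixed)))
    fixed$a_scale <- 0

  assign_mat <- matrix(NA_integer_, nc, 4,
                       dimnames = list(NULL, names(grouping)))
  fixed_mat <- matrix(NA_real_, nc, 4,
                      dimnames = list(NULL, names(grouping)))
  slots <- list()
  next_slot <- 0L
  allo_cell <- cells$condition %in% allo_conditions

  for (par in names(grouping)) {
    eligible <- if (par %in% c("a_max", "a_scale")) allo_cell else rep(TRUE, nc)
    if (par %in% c("a_max", "a_scale")) fixed_mat[!eligible, par] <- 0
    if (!any(eligible)) next
    if (par %in% names(fixed)) {
      fixed_mat[eligible, par] <- as.numeric(fixed[[par]])
      next
    }
    g <- grouping[[par]]
    if (is.numeric(g)) { fixed_mat[eligible, par] <- g; next }
    labels <- switch(match.arg(g, c("shared", "by_set_size", "by_condition",
                                    "by_cell")),
      shared       = rep("all", nc),
      by_set_size  = paste0("ss", cells$set_size),
      by_condition = cells$condition,
      by_cell      = .cell_key(cells$condition, cells$set_size))
    for (lab in unique(labels[eligible])) {
      next_slot <- next_slot + 1L
      members <- eligible & labels == lab
      assign_mat[members, par] <- next_slot
      slots[[next_slot]] <- data.frame(
        slot = next_slot, param = par, group = lab,
        lower = default_bounds[[par]][1], upper = default_bounds[[par]][2],
        stringsAsFactors = FALSE)
    }
  }

  cost_slot <- NA_integer_
  if (cost) {
    if (is.null(cost_conditions))
      cost_conditions <- setdiff(.CONDITIONS, "LM_ABSENT")
    if (!any(cells$condition %in% cost_conditions) ||
        !any(!cells$condition %in% cost_conditions))
      stop("cost model needs both costed and cost-free cells in the data")
    next_slot <- next_slot + 1L
    cost_slot <- next_slot
    slots[[next_slot]] <- data.frame(
      slot = next_slot, param = "cost", group = "all",
      lower = default_bounds$cost[1], upper = default_bounds$cost[2],
      stringsAsFactors = FALSE)
  } else cost_conditions <- character(0)

  slots <- if (length(slots)) do.call(rbind, slots) else
    data.frame(slot = integer(0), param = character(0), group = character(0),
               lower = numeric(0), upper = numeric(0))
  structure(list(cells = cells, slots = slots, assign = assign_mat,
                 fixed_values = fixed_mat, k = nrow(slots),
                 allo_conditions = allo_conditions,
                 cost_slot = cost_slot, cost_conditions = cost_conditions,
                 shift_reference = shift_reference),
            class = "param_tying")
}

#' @export
print.param_tying <- function(x, ...) {
  cat(sprintf("Parameter tying over %d cell(s), k = %d free parameter(s)\n",
              nrow(x$cells), x$k))
  if (x$k > 0) {
    lab <- paste0(x$slots$param, "[", x$slots$group, "]")
    cat("  slots:", paste(lab, collapse = ", "), "\n")
  }
  fixed <- which(!is.na(x$fixed_values), arr.ind = TRUE)
  if (nrow(fixed)) {
    f <- unique(data.frame(param = colnames(x$fixed_values)[fixed[, 2]],
                           value = x$fixed_values[fixed]))
    cat("  fixed:", paste(sprintf("%s=%g", f$param, f$value),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate the condition/set-size cells of a dataset
#'
#' @param data a trial data frame with `condition` and `set_size` columns.
#' @return data frame of unique cells, ordered.
#' @export
dataset_cells <- function(data) {
  cells <- unique(data[, c("condition", "set_size")])
  cells <- cells[order(cells$condition, cells$set_size), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Standard model variants
#'
#' `tying_full()` is the optimal-integration model (allocentric component free
#' in landmark conditions); `tying_reduced()` removes the allocentric
#' component entirely (`a_max` fixed at 0); `tying_cost()` is the
#' five-parameter cost variant with every parameter shared across cells plus
#' a proportional egocentric cost of landmark presence.
#'
#' @param cells cell table, see [dataset_cells()].
#' @param ... passed on to [param_tying()].
#' @return a `param_tying` object.
#' @export
tying_full <- function(cells, ...) param_tying(cells, ...)

#' @rdname tying_full
#' @export
tying_reduced <- function(cells, ...) {
  args <- list(...)
  fixed <- args$fixed %||% list()
  fixed$a_max <- 0
  args$fixed <- fixed
  do.call(param_tying, c(list(cells = cells), args))
}

#' @rdname tying_full
#' @export
tying_cost <- function(cells, ...) {
  param_tying(cells, p_ego = "shared", a_max = "shared", a_scale = "shared",
              p_lapse = "shared", cost = TRUE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-cell observer_params implied by a slot-value vector
.resolve_cell_params <- function(tying, values) {
  if (length(values) != tying$k)
    stop("expected ", tying$k, " parameter values, got ", length(values))
  nc <- nrow(tying$cells)
  cost_val <- if (!is.na(tying$cost_slot)) values[tying$cost_slot] else 0
  out <- vector("list", nc)
  for (i in seq_len(nc)) {
    get <- function(par) {
      s <- tying$assign[i, par]
      if (!is.na(s)) values[s] else tying$fixed_values[i, par]
    }
    p_ego <- get("p_ego")
    if (cost_val != 0 && tying$cells$condition[i] %in% tying$cost_conditions)
      p_ego <- p_ego * (1 - cost_val)
    out[[i]] <- model_params(p_ego = p_ego, a_max = get("a_max"),
                             a_scale = get("a_scale"),
                             p_lapse = get("p_lapse"), cost = cost_val)
  }
  names(out) <- .cell_key(tying$cells$condition, tying$cells$set_size)
  out
}
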
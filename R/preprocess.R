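# Model preparation for balancing analysis: blocked-reaction removal, bound
# normalization and the flux-balance optimum.

#' Find blocked reactions
#'
#' A reaction is blocked when its flux is numerically zero in every steady
#' state of the flux space: both the FVA maximum and the absolute FVA minimum
#' fall below `tol` (default 1e-9, the conventional threshold in
#' mmol/gDW/h). For spaces without extra constraints and with zero lower
#' bounds the minimum is zero by construction and only the maximization LP is
#' solved.
#'
#' @param model a split (irreversible) `network_model`.
#' @param fspace the flux space to test in; defaults to `flux_space(model)`.
#' @param tol positive blocking threshold.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, fspace = flux_space(model), tol = 1e-9) {
  stopifnot(tol > 0)
  ids <- model$reactions$id
  need_min <- !is.null(fspace$extra) || any(fspace$vmin > 0)
  blocked <- vapply(seq_along(ids), function(i) {
    obj <- stats::setNames(1, ids[i])
    hi <- solve_lp(fspace, obj, maximize = TRUE)
    if (hi$status != "optimal") rlang::abort("infeasible flux space in blocked-reaction analysis")
    if (abs(hi$value) >= tol) return(FALSE)
    lo_val <- if (need_min) {
      lo <- solve_lp(fspace, obj, maximize = FALSE)
      if (lo$status != "optimal") rlang::abort("infeasible flux space in blocked-reaction analysis")
      lo$value
    } else 0
    abs(lo_val) < tol
  }, logical(1))
  ids[blocked]
}

#' Flux-balance-analysis optimum
#'
#' Maximizes the flux of the objective reaction over the flux space.
#'
#' @param model a split `network_model`.
#' @param fspace a `flux_space` (default: from the model bounds).
#' @param objective objective reaction id; defaults to `model$objective`.
#' @return list with `value`, `solution`, `status`. The status is
#'   `"unbounded"` when the objective's upper bound was infinite and the
#'   optimum sits on the internal cap.
#' @export
fba_optimum <- function(model, fspace = flux_space(model), objective = model$objective) {
  if (is.null(objective) || is.na(objective)) rlang::abort("no objective reaction")
  j <- match(objective, fspace$reaction_ids)
  if (is.na(j)) rlang::abort(sprintf("objective '%s' not in flux space", objective))
  res <- solve_lp(fspace, stats::setNames(1, objective), maximize = TRUE)
  if (res$status != "optimal") return(list(value = NA_real_, solution = NULL, status = res$status))
  if (fspace$capped[j] && res$value >= fspace$vmax[j] - 1e-9) {
    res$status <- "unbounded"
  }
  res
}

#' Impose a biomass floor on a flux space
#'
#' Adds the constraint `v_objective >= fraction * optimum`. Following common
#' practice the optimum is computed on the flux space before blocked-reaction
#' removal unless supplied.
#'
#' @param fspace a `flux_space`.
#' @param objective objective reaction id.
#' @param fraction value in `[0, 1]`.
#' @param optimum the FBA optimum to scale; computed on `fspace` when `NULL`.
#' @return the constrained `flux_space`. A `fraction` of zero returns the
#'   space unchanged.
#' @export
biomass_floor <- function(fspace, objective, fraction = 0.05, optimum = NULL) {
  stopifnot(inherits(fspace, "flux_space"), fraction >= 0, fraction <= 1)
  if (fraction == 0) return(fspace)
  if (is.null(optimum)) {
    res <- solve_lp(fspace, stats::setNames(1, objective), maximize = TRUE)
    if (res$status != "optimal") rlang::abort("cannot compute FBA optimum for biomass floor")
    optimum <- res$value
  }
  row <- tibble::tibble(
    coef = list(stats::setNames(1, objective)),
    rel = ">=",
    rhs = fraction * optimum)
  fspace$extra <- dplyr::bind_rows(fspace$extra, row)
  # fail fast if the floored polytope is empty
  chk <- solve_lp(fspace, stats::setNames(1, objective), maximize = TRUE)
  if (chk$status != "optimal") rlang::abort("biomass floor renders the flux space infeasible")
  fspace
}

#' Prepare a model for balancing analysis
#'
#' Runs the standard preprocessing pipeline: split reversible reactions
#' (normalizing bounds), compute the FBA optimum if an objective is present
#' (on the model still containing blocked reactions), remove blocked
#' reactions (dropping orphaned complexes and species), and optionally floor
#' the biomass flux at a fraction of its optimum.
#'
#' @param model a `network_model` (may contain reversible reactions).
#' @param mode reversibility handling passed to [split_reversible()].
#' @param tol blocked-reaction threshold.
#' @param biomass_fraction when non-zero and an objective exists, lower-bounds
#'   the objective flux at this fraction of the optimum.
#' @return list with `model` (split, blocked-free), `fspace` (its flux space,
#'   including any biomass floor), `fba` (optimum or `NA`), and `removed`
#'   (blocked reaction ids).
#' @export
prepare_model <- function(model, mode = c("keep", "all-reversible"),
                          tol = 1e-9, biomass_fraction = 0) {
  mode <- match.arg(mode)
  split <- split_reversible(model, mode = mode)
  fs0 <- flux_space(split)
  opt <- NA_real_
  if (!is.na(split$objective)) {
    res <- fba_optimum(split, fs0)
    opt <- res$value
  }
  blocked <- find_blocked_reactions(split, fs0, tol = tol)
  pruned <- if (length(blocked)) drop_reactions(split, blocked) else split
  fs <- flux_space(pruned)
  if (biomass_fraction > 0) {
    if (is.na(pruned$objective)) rlang::abort("biomass floor requested but the model has no objective")
    fs <- biomass_floor(fs, pruned$objective, biomass_fraction, optimum = opt)
  }
  list(model = pruned, fspace = fs, fba = opt, removed = blocked)
}
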
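# Validation protocols: steady-state and conservation-law preservation,
# growth, flux-variability and essentiality comparisons between an original
# model and its reduction.

#' Check conservation-law inclusion ker(N') subset of ker(Nbar')
#'
#' Every new reaction inserted during reduction is a sum of original reaction
#' columns, so the column span of the reduced stoichiometric matrix lies in
#' that of the original and every conservation law (moiety vector lambda with
#' `lambda' N = 0`) of the original network is preserved in the reduced one.
#' This check computes a basis of the left null space of `N`, lifts the
#' reduced matrix back to the original species rows (zero rows for removed
#' species, whose coefficients are expressible through the recorded
#' substitutions), and verifies `lambda' Nbar = 0` for every basis vector.
#' The converse need not hold: the reduced network may have additional laws.
#'
#' @param original,reduced `network_model`s (the reduced one produced from
#'   the original by [reduce_network()]).
#' @param tol numerical tolerance on the residual.
#' @return list with `ok` (logical), `max_residual`, `basis` (left-null basis
#'   of `N`, species in rows) and `witness` (a violating vector, or `NULL`).
#' @export
check_conservation_inclusion <- function(original, reduced, tol = 1e-8) {
  N <- as.matrix(stoichiometric_matrix(original))
  basis <- left_null_basis(N)
  if (ncol(basis) == 0L) {
    return(list(ok = TRUE, max_residual = 0, basis = basis, witness = NULL))
  }
  Nr <- as.matrix(stoichiometric_matrix(reduced))
  if (ncol(Nr) == 0L) {
    # everything reduced away: no reaction left to violate a law
    return(list(ok = TRUE, max_residual = 0, basis = basis, witness = NULL))
  }
  lift <- matrix(0, nrow(N), ncol(Nr))
  rows <- match(reduced$species$id, original$species$id)
  if (anyNA(rows)) rlang::abort("reduced model contains species absent from the original")
  lift[rows, ] <- Nr
  res <- crossprod(basis, lift)                 # basis' %*% Nbar_lifted
  scale <- max(1, max(abs(N)))
  max_res <- if (length(res)) max(abs(res)) else 0
  bad <- which(apply(abs(res), 1, max) > tol * scale)
  list(ok = length(bad) == 0L,
       max_residual = max_res,
       basis = basis,
       witness = if (length(bad)) basis[, bad[1]] else NULL)
}

# orthonormal basis of {x : x' M = 0} via SVD, rank tolerance scaled by the
# leading singular value and matrix size
left_null_basis <- function(M) {
  if (nrow(M) == 0L) return(matrix(0, 0, 0))
  sv <- svd(M, nu = nrow(M), nv = 0)
  tol <- max(dim(M)) * .Machine$double.eps * (if (length(sv$d)) max(sv$d, 1) else 1)
  rank <- sum(sv$d > tol)
  if (rank >= nrow(M)) matrix(0, nrow(M), 0) else sv$u[, (rank + 1):nrow(M), drop = FALSE]
}

#' Check that sampled steady states survive the reduction
#'
#' Samples vertices of the original flux space by maximizing seeded random
#' objectives, maps each sample through the recorded flux substitutions and
#' verifies `Nbar vbar = 0` on the reduced model.
#'
#' @param result a `reduction_result` with numeric flux maps (arbitrary
#'   kinetics or numeric mass-action shares).
#' @param fspace flux space of the original model; defaults to its bounds.
#' @param n_samples number of sampled flux distributions.
#' @param seed integer seed for the random objectives.
#' @return list with `ok`, `max_residual` and `n_samples`.
#' @export
check_steady_state_preserved <- function(result, fspace = flux_space(result$original),
                                         n_samples = 50, seed = 1L) {
  stopifnot(inherits(result, "reduction_result"), n_samples >= 1)
  Nr <- stoichiometric_matrix(result$model)
  set.seed(seed)
  n <- length(fspace$reaction_ids)
  max_res <- 0
  for (s in seq_len(n_samples)) {
    obj <- stats::rnorm(n)
    sol <- solve_lp(fspace, obj, maximize = TRUE)
    if (sol$status != "optimal") rlang::abort("original flux space infeasible")
    vbar <- apply_flux_map(result, sol$solution)
    res <- max(abs(as.numeric(Nr %*% vbar)))
    max_res <- max(max_res, res)
  }
  list(ok = max_res < 1e-9, max_residual = max_res, n_samples = n_samples)
}

#' Check mass-action concentration preservation
#'
#' Given a steady state `x*` of the original mass-action network
#' (`N K phi(x*) = 0`), verifies that its restriction to the surviving
#' species satisfies the reduced network's steady-state equations
#' `Nbar Kbar phibar(x*) = 0`.
#'
#' @param result a `reduction_result` from mass-action reduction with numeric
#'   kinetics.
#' @param kinetics the original numeric kinetics (used to report the original
#'   residual alongside).
#' @param x_star named steady-state concentration vector of the original
#'   model.
#' @param tol residual tolerance for the reduced equations.
#' @return list with `ok`, `residual_original`, `residual_reduced`.
#' @export
check_concentration_preserved <- function(result, kinetics, x_star, tol = 1e-8) {
  stopifnot(inherits(result, "reduction_result"))
  orig <- mass_action_rates(result$original, kinetics, x_star)
  if (nrow(result$model$reactions) == 0L) {
    return(list(ok = TRUE, residual_original = max(abs(orig$dx)), residual_reduced = 0))
  }
  x_red <- x_star[result$model$species$id]
  red <- mass_action_rates(result$model, result$kinetics, x_red)
  res_red <- if (length(red$dx)) max(abs(red$dx)) else 0
  list(ok = res_red < tol,
       residual_original = max(abs(orig$dx)),
       residual_reduced = res_red)
}

#' Compare flux variability between original and reduced models
#'
#' Flux variability analysis at a fraction of the optimal objective flux, for
#' all reactions present in both models, with a per-reaction classification
#' of the range change.
#'
#' @param original,reduced split, blocked-free `network_model`s sharing the
#'   objective reaction.
#' @param fraction objective floor as a fraction of each model's optimum
#'   (default 0.99).
#' @param tol tolerance for calling two range endpoints equal.
#' @return tibble with per-reaction FVA ranges in both models and a
#'   `classification` column (`same_range`, `wider`, `narrower`, `mixed`).
#' @export
compare_fva <- function(original, reduced, fraction = 0.99, tol = 1e-6) {
  obj <- original$objective
  if (is.na(obj) || is.na(reduced$objective)) {
    rlang::abort("both models need an objective; use a protected reduction")
  }
  shared <- intersect(original$reactions$id, reduced$reactions$id)
  r1 <- fva_at_optimum(original, fraction, shared)
  r2 <- fva_at_optimum(reduced, fraction, shared)
  out <- dplyr::left_join(r1, r2, by = "id", suffix = c("_original", "_reduced"))
  cls <- function(lo1, hi1, lo2, hi2) {
    same_lo <- abs(lo1 - lo2) <= tol * max(1, abs(lo1))
    same_hi <- abs(hi1 - hi2) <= tol * max(1, abs(hi1))
    if (same_lo && same_hi) return("same_range")
    wider <- lo2 <= lo1 + tol && hi2 >= hi1 - tol
    narrower <- lo2 >= lo1 - tol && hi2 <= hi1 + tol
    if (wider && !narrower) "wider" else if (narrower && !wider) "narrower" else "mixed"
  }
  out$classification <- mapply(cls, out$min_original, out$max_original,
                               out$min_reduced, out$max_reduced)
  out
}

fva_at_optimum <- function(model, fraction, reactions) {
  fs <- flux_space(model)
  opt <- fba_optimum(model, fs)
  if (opt$status != "optimal") rlang::abort("FBA failed in FVA comparison")
  fs <- biomass_floor(fs, model$objective, fraction, optimum = opt$value)
  fva(fs, reactions)
}

#' Compare reaction essentiality between original and reduced models
#'
#' Knocks out each shared reaction (bounds set to zero) in both models and
#' classifies it as essential when the knockout optimum falls below
#' `threshold` times the wild-type optimum. Reactions introduced by the
#' reduction (present only in the reduced model) are evaluated there as well.
#'
#' @param original,reduced `network_model`s sharing the objective.
#' @param threshold essentiality cut-off as a fraction of wild type
#'   (default 0.01).
#' @return tibble with columns `id`, `shared`, `essential_original`,
#'   `essential_reduced`.
#' @export
compare_essentiality <- function(original, reduced, threshold = 0.01) {
  if (is.na(original$objective) || is.na(reduced$objective)) {
    rlang::abort("both models need an objective")
  }
  ess <- function(model) {
    fs <- flux_space(model)
    wt <- fba_optimum(model, fs)$value
    vapply(model$reactions$id, function(r) {
      if (r == model$objective) return(TRUE)
      ko <- model
      i <- match(r, ko$reactions$id)
      ko$reactions$lb[i] <- 0
      ko$reactions$ub[i] <- 0
      val <- fba_optimum(ko, flux_space(ko))$value
      is.na(val) || val < threshold * wt
    }, logical(1))
  }
  e1 <- ess(original)
  e2 <- ess(reduced)
  ids <- union(original$reactions$id, reduced$reactions$id)
  tibble::tibble(
    id = ids,
    shared = ids %in% original$reactions$id & ids %in% reduced$reactions$id,
    essential_original = unname(e1[ids]),
    essential_reduced = unname(e2[ids]))
}

#' Jaccard similarity of two identifier sets
#'
#' `|A intersect B| / |A union B|`; two empty sets compare as identical
#' (similarity 1).
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return value in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-compartment species reduction statistics
#'
#' @param original,reduced `network_model`s with compartment labels on the
#'   species (unlabelled species are grouped under `"unassigned"`).
#' @return tibble with columns `compartment`, `species_original`,
#'   `species_reduced`, `percent_removed`.
#' @export
compartment_reduction_stats <- function(original, reduced) {
  comp <- function(m) {
    cc <- m$species$compartment
    cc[is.na(cc) | cc == ""] <- "unassigned"
    tibble::tibble(compartment = cc, id = m$species$id)
  }
  before <- dplyr::count(comp(original), .data$compartment, name = "species_original")
  after <- dplyr::count(comp(reduced), .data$compartment, name = "species_reduced")
  out <- dplyr::left_join(before, after, by = "compartment")
  out$species_reduced[is.na(out$species_reduced)] <- 0L
  out$percent_removed <- 100 * (out$species_original - out$species_reduced) / out$species_original
  out
}
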
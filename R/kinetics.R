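# Mass-action kinetics: rate-constant bookkeeping, the reactions x complexes
# constant matrix K, and the monomial evaluator phi(x).
#
# Under mass action the flux of reaction i with substrate complex y(i) is
# v_i = k_i * x^y(i), where x^y(i) is the product of substrate concentrations
# raised to their stoichiometries; the network dynamics are dx/dt = N K phi(x)
# with phi(x) the vector of complex monomials.

#' Rate-constant matrix K
#'
#' Builds the reactions x complexes matrix whose entry `(i, j)` is the rate
#' constant of reaction `i` when complex `j` is its substrate complex and zero
#' otherwise (exactly one nonzero per row, matching the -1 pattern of `t(A)`).
#'
#' @param model a `network_model`.
#' @param kinetics named numeric vector of positive rate constants keyed by
#'   reaction id; must cover all reactions.
#' @return sparse matrix K.
#' @export
kinetics_matrix <- function(model, kinetics) {
  k <- kinetics_for(model, kinetics, model$reactions$id)
  Matrix::sparseMatrix(
    i = seq_len(nrow(model$reactions)),
    j = model$reactions$substrate,
    x = unname(k),
    dims = c(nrow(model$reactions), nrow(model$complexes)),
    dimnames = list(model$reactions$id, NULL))
}

kinetics_for <- function(model, kinetics, ids) {
  if (is.null(kinetics)) rlang::abort("numeric kinetics required")
  miss <- setdiff(ids, names(kinetics))
  if (length(miss)) {
    rlang::abort(sprintf("kinetics missing for reaction(s): %s", paste(miss, collapse = ", ")))
  }
  k <- kinetics[ids]
  if (is.numeric(k) && any(k <= 0)) rlang::abort("rate constants must be positive")
  k
}

#' Complex monomials phi(x)
#'
#' Evaluates `x^y` for every complex: the product over species of the
#' concentration raised to the stoichiometry with which the species enters
#' the complex. The empty complex evaluates to 1.
#'
#' @param model a `network_model`.
#' @param x named (or model-ordered) vector of non-negative concentrations.
#' @return numeric vector over complexes.
#' @export
complex_monomials <- function(model, x) {
  if (!is.null(names(x))) x <- x[model$species$id]
  stopifnot(length(x) == nrow(model$species))
  x <- pmax(as.numeric(x), 0)
  vapply(model$complexes$composition, function(comp) {
    if (length(comp) == 0L) return(1)
    prod(x[match(names(comp), model$species$id)]^unname(comp))
  }, numeric(1))
}

#' Mass-action fluxes and species rates
#'
#' @param model a `network_model`.
#' @param kinetics named numeric rate constants.
#' @param x concentration vector.
#' @return list with `v` (per-reaction fluxes `k_i x^y(i)`) and `dx`
#'   (species rates `N v`).
#' @export
mass_action_rates <- function(model, kinetics, x) {
  k <- kinetics_for(model, kinetics, model$reactions$id)
  phi <- complex_monomials(model, x)
  v <- unname(k) * phi[model$reactions$substrate]
  names(v) <- model$reactions$id
  dx <- as.numeric(stoichiometric_matrix(model) %*% v)
  names(dx) <- model$species$id
  list(v = v, dx = dx)
}
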
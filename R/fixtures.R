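# Built-in networks, synthetic generators and independent oracles.

#' The six-species worked-example network
#'
#' A small irreversible network of six species (A-F), eight complexes and ten
#' reactions (v1-v10) used throughout the package's examples and tests. Its
#' structure pins down the balancing classification completely: species D, E
#' and F each occur in a single complex, so D, A+E and F are trivially
#' balanced; 2A is non-trivially balanced (A occurs only in 2A and the
#' trivially balanced A+E); complex C is a sink; the incoming neighbourhood
#' of 2B is {D, F} and its outgoing neighbourhood {A+E, F}; 2A, A+E and F
#' have a single outgoing reaction while D has two. All ten reactions carry
#' flux in some steady state (no blocked reactions) with bounds `[0, 10]`.
#'
#' The default rate constants attached as the `"kinetics"` attribute are
#' chosen so that the all-ones concentration vector is a positive steady
#' state of the mass-action dynamics.
#'
#' @return a `network_model`; `attr(, "kinetics")` carries the default
#'   mass-action rate constants.
#' @examples
#' toy <- toy_network()
#' nrow(toy$complexes) # 8
#' @export
toy_network <- function() {
  rxn <- tibble::tibble(
    id = paste0("v", 1:10),
    substrates = c("D", "F", "2 B", "2 B", "A + E", "D", "B", "2 A", "B + C", "B + C"),
    products   = c("2 B", "2 B", "A + E", "F", "D", "B", "2 A", "B + C", "C", "D"),
    lb = 0, ub = 10)
  model <- build_complexes(rxn)
  attr(model, "kinetics") <- toy_kinetics()
  model
}

#' Default mass-action rate constants of the worked-example network
#'
#' Constants for which the all-ones state is a positive steady state: with
#' every monomial equal to one, the fluxes equal the constants, and the
#' constant vector is itself a steady-state flux distribution.
#'
#' @return named numeric vector over reactions v1-v10.
#' @export
toy_kinetics <- function() {
  stats::setNames(c(2, 1, 1, 1, 1, 1, 2, 2, 1, 2), paste0("v", 1:10))
}

#' A minimal growth model fixture
#'
#' A six-reaction model with an uptake reaction, two routes from the carbon
#' source A to the biomass precursor B (one direct, one through a removable
#' intermediate Q), a recycling reaction `2 B -> A`, and a biomass objective
#' `B -> 0`. The intermediate complex Q is trivially balanced with a single
#' outgoing reaction and contains no biomass precursor, so a
#' biomass-protected reduction removes exactly Q while the growth optimum is
#' untouched; the recycling reaction keeps the empty complex unbalanced, so
#' the uptake reaction survives the reduction and is essential in both
#' models.
#'
#' @return a `network_model` with objective `"bio"`.
#' @export
growth_network <- function() {
  rxn <- tibble::tibble(
    id = c("upt", "c1", "r4", "r5", "r6", "bio"),
    substrates = c("", "A", "A", "Q", "2 B", "B"),
    products = c("A", "B", "Q", "B", "A", ""),
    lb = 0, ub = 10)
  build_complexes(rxn, objective = "bio")
}

#' Specification for a planted random mass-action network
#'
#' @param n_species total species count (shared pool plus one unique species
#'   per planted complex).
#' @param n_complexes number of complexes.
#' @param n_reactions number of reactions; must be even (reactions are
#'   generated as reversible pairs) and at least `2 * (n_complexes - 1)` so a
#'   connected complex graph exists.
#' @param n_planted_trivial number of planted trivially balanced complexes,
#'   each containing a species unique to it.
#' @param max_stoichiometry largest stoichiometric coefficient.
#' @param rate_constant_range positive interval for the log-uniform forward
#'   rate constants.
#' @param seed integer seed.
#' @return a `planted_network_spec` list.
#' @export
planted_network_spec <- function(n_species = 6, n_complexes = 5, n_reactions = 10,
                                 n_planted_trivial = 1, max_stoichiometry = 2,
                                 rate_constant_range = c(0.1, 10), seed = 1L) {
  spec <- list(n_species = n_species, n_complexes = n_complexes,
               n_reactions = n_reactions, n_planted_trivial = n_planted_trivial,
               max_stoichiometry = max_stoichiometry,
               rate_constant_range = rate_constant_range, seed = seed)
  if (n_reactions %% 2 != 0) rlang::abort("n_reactions must be even (reversible pairs)")
  if (n_reactions < 2 * (n_complexes - 1)) {
    rlang::abort("n_reactions too small for a connected complex graph")
  }
  if (n_planted_trivial >= n_complexes) rlang::abort("too many planted complexes")
  if (n_planted_trivial >= n_species) rlang::abort("planted complexes need unique species")
  structure(spec, class = "planted_network_spec")
}

#' Generate a random mass-action network with planted balanced complexes
#'
#' Generates a connected complex graph (random spanning tree plus extra
#' edges) in which every reaction comes as a reversible pair, so no reaction
#' is blocked and every complex has incoming and outgoing reactions. The
#' first `n_planted_trivial` complexes each contain a species unique to them
#' and are therefore trivially balanced by construction. Rate constants
#' satisfy detailed balance at a planted positive state `x_star`: forward
#' constants are log-uniform on `rate_constant_range` and each backward
#' constant is chosen so the pair's net flux vanishes at `x_star`, which
#' makes `x_star` a complex-balanced steady state and guarantees the
#' mass-action dynamics converge.
#'
#' @param spec a [planted_network_spec()].
#' @return list with `model`, `kinetics` (named numeric), `planted`
#'   (indices of the planted trivially balanced complexes) and `x_star`
#'   (the planted steady state).
#' @export
random_mass_action_network <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  set.seed(spec$seed)
  nc <- spec$n_complexes
  n_edges <- spec$n_reactions / 2
  n_uniq <- spec$n_planted_trivial
  shared <- paste0("S", seq_len(spec$n_species - n_uniq))
  uniq <- if (n_uniq > 0) paste0("U", seq_len(n_uniq)) else character(0)

  # distinct complex compositions: planted ones first
  comps <- list()
  keys <- character(0)
  for (i in seq_len(n_uniq)) {
    comp <- stats::setNames(sample.int(spec$max_stoichiometry, 1), uniq[i])
    if (stats::runif(1) < 0.5 && length(shared)) {
      extra <- sample(shared, 1)
      comp <- c(comp, stats::setNames(sample.int(spec$max_stoichiometry, 1), extra))
    }
    comps[[i]] <- comp[order(names(comp))]
    keys[i] <- complex_key(comps[[i]])
  }
  guard <- 0
  while (length(comps) < nc) {
    guard <- guard + 1
    if (guard > 1000) rlang::abort("could not generate enough distinct complexes")
    k <- sample.int(min(2, length(shared)), 1)
    sp <- sample(shared, k)
    comp <- stats::setNames(sample.int(spec$max_stoichiometry, k, replace = TRUE), sp)
    comp <- comp[order(names(comp))]
    key <- complex_key(comp)
    if (key %in% keys) next
    comps[[length(comps) + 1L]] <- comp
    keys <- c(keys, key)
  }

  # connected digraph: random spanning tree, then extra distinct edges
  edges <- matrix(0L, 0, 2)
  perm <- sample.int(nc)
  for (i in seq_len(nc - 1)) {
    a <- perm[i + 1]; b <- perm[sample.int(i, 1)]
    edges <- rbind(edges, c(a, b))
  }
  guard <- 0
  while (nrow(edges) < n_edges) {
    guard <- guard + 1
    if (guard > 2000) rlang::abort("could not place the requested number of edges")
    e <- sample.int(nc, 2)
    dup <- any(edges[, 1] == e[1] & edges[, 2] == e[2]) ||
      any(edges[, 1] == e[2] & edges[, 2] == e[1])
    if (dup) next
    edges <- rbind(edges, e)
  }

  sides <- vapply(comps, format_side, "")
  rxn <- tibble::tibble(
    id = paste0("r", seq_len(nrow(edges))),
    substrates = sides[edges[, 1]],
    products = sides[edges[, 2]],
    lb = 0, ub = 10, reversible = TRUE)
  model0 <- build_complexes(rxn)
  model <- split_reversible(model0, mode = "keep")

  # detailed-balance constants at a planted positive state
  sp_ids <- model$species$id
  x_star <- stats::setNames(stats::runif(length(sp_ids), 0.5, 2), sp_ids)
  lr <- log(spec$rate_constant_range)
  phi <- complex_monomials(model, x_star)
  kin <- numeric(nrow(model$reactions))
  names(kin) <- model$reactions$id
  for (i in seq_len(nrow(edges))) {
    kf <- exp(stats::runif(1, lr[1], lr[2]))
    sub_j <- model$reactions$substrate[2 * i - 1]
    prod_j <- model$reactions$product[2 * i - 1]
    kb <- kf * phi[sub_j] / phi[prod_j]
    kin[2 * i - 1] <- kf
    kin[2 * i] <- kb
  }

  planted <- match(keys[seq_len(n_uniq)], model$complexes$key)
  list(model = model, kinetics = kin, planted = planted, x_star = x_star)
}

#' Brute-force balanced complexes by vertex enumeration
#'
#' Independent oracle for the LP-based identification: enumerates all
#' vertices of the bounded polytope `{N v = 0, vmin <= v <= vmax}` by basis
#' enumeration (every vertex fixes at least `n - rank(N)` coordinates at a
#' bound; all such coordinate subsets and bound assignments are solved in
#' batch), and declares a complex balanced exactly when its net flux
#' `[A v]_i` vanishes at every vertex. Linearity of the net flux makes the
#' vertex check exhaustive for the whole polytope.
#'
#' @param model a split `network_model`.
#' @param fspace its `flux_space` (extra constraints are not supported here).
#' @param tol zero tolerance at vertices.
#' @param max_reactions dimension guard; enumeration is exponential.
#' @return integer vector of balanced complex indices.
#' @export
brute_force_balanced <- function(model, fspace = flux_space(model), tol = 1e-9,
                                 max_reactions = 14L) {
  if (!is.null(fspace$extra) && nrow(fspace$extra)) {
    rlang::abort("vertex enumeration supports plain box/steady-state spaces only")
  }
  n <- length(fspace$reaction_ids)
  if (n > max_reactions) rlang::abort("network too large for vertex enumeration")
  V <- enumerate_vertices(as.matrix(fspace$N), fspace$vmin, fspace$vmax)
  if (ncol(V) == 0L) rlang::abort("flux polytope has no vertices (infeasible?)")
  A <- as.matrix(incidence_matrix(model))
  net <- A %*% V
  which(apply(abs(net), 1, max) < tol)
}

# all vertices of {Nv = 0, lb <= v <= ub}, columns of the returned matrix
enumerate_vertices <- function(N, lb, ub, tol = 1e-9) {
  n <- ncol(N)
  qrN <- qr(N)
  r <- qrN$rank
  d <- n - r
  verts <- list()
  push <- function(v) verts[[length(verts) + 1L]] <<- v
  if (d == 0L) {
    v <- qr.solve(qrN, rep(0, nrow(N)))
    if (all(v >= lb - tol & v <= ub + tol)) push(v)
  } else {
    combos <- utils::combn(n, d)
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))  # 0 = lower, 1 = upper
    for (ci in seq_len(ncol(combos))) {
      fixed <- combos[, ci]
      free <- setdiff(seq_len(n), fixed)
      NG <- N[, free, drop = FALSE]
      qrG <- qr(NG)
      if (qrG$rank < length(free)) next
      Vfix <- t(grid) * (ub[fixed] - lb[fixed]) + lb[fixed]  # d x 2^d
      RHS <- -N[, fixed, drop = FALSE] %*% Vfix
      X <- qr.coef(qrG, RHS)
      X[is.na(X)] <- 0
      resid <- NG %*% X - RHS
      ok <- colSums(abs(resid)) < 1e-8
      if (!any(ok)) next
      for (g in which(ok)) {
        v <- numeric(n)
        v[fixed] <- Vfix[, g]
        v[free] <- X[, g]
        if (all(v >= lb - tol & v <= ub + tol)) push(v)
      }
    }
  }
  if (!length(verts)) return(matrix(0, n, 0))
  V <- do.call(cbind, verts)
  V <- round(V / 1e-8) * 1e-8
  unique_cols(V)
}

unique_cols <- function(M) {
  keys <- apply(M, 2, paste, collapse = ",")
  M[, !duplicated(keys), drop = FALSE]
}

#' Integrate mass-action dynamics to steady state
#'
#' Integrates `dx/dt = N K phi(x)` with a stiff-capable solver until the
#' infinity norm of the rate vector falls below `tol` (detected by a root
#' function), doubling the time horizon as needed up to `t_max`.
#'
#' @param model a `network_model`.
#' @param kinetics named numeric rate constants.
#' @param x0 positive named initial concentrations.
#' @param tol steady-state residual tolerance.
#' @param t_max maximum integration time.
#' @return named concentration vector with attribute `"residual"`.
#' @export
simulate_to_steady_state <- function(model, kinetics, x0, tol = 1e-10, t_max = 1e6) {
  stopifnot(all(x0 > 0))
  k <- kinetics_for(model, kinetics, model$reactions$id)
  N <- as.matrix(stoichiometric_matrix(model))
  sub_idx <- model$reactions$substrate
  comps <- model$complexes$composition
  sp_ids <- model$species$id
  x0 <- x0[sp_ids]

  rhs <- function(t, x, parms) {
    xx <- pmax(x, 0)
    phi <- vapply(comps, function(comp) {
      if (length(comp) == 0L) return(1)
      prod(xx[match(names(comp), sp_ids)]^unname(comp))
    }, numeric(1))
    list(as.numeric(N %*% (unname(k) * phi[sub_idx])))
  }
  root <- function(t, x, parms) {
    max(abs(rhs(t, x, parms)[[1]])) - tol
  }
  t_end <- 10
  x <- x0
  repeat {
    out <- suppressWarnings(
      deSolve::lsodar(y = x, times = c(0, t_end), func = rhs, parms = NULL,
                      rootfunc = root, rtol = 1e-10, atol = 1e-12,
                      maxsteps = 50000))
    x <- out[nrow(out), -1]
    res <- max(abs(rhs(0, x, NULL)[[1]]))
    if (res < tol) break
    if (t_end >= t_max) {
      rlang::abort(sprintf("no steady state reached by t = %g (residual %.3g)", t_max, res))
    }
    t_end <- t_end * 4
  }
  x <- stats::setNames(as.numeric(x), sp_ids)
  attr(x, "residual") <- res
  x
}
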
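#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by summarise ungroup distinct
#' @importFrom Matrix sparseMatrix Matrix t rowSums colSums
NULL

# ---- complex compositions ------------------------------------------------

#' Parse one side of a reaction equation
#'
#' Turns a string such as `"2 A + E"` into a named numeric vector of
#' stoichiometric coefficients (`c(A = 2, E = 1)`). The empty string denotes
#' the empty complex (used by exchange reactions) and parses to a zero-length
#' vector. Coefficients may be fractional (biomass compositions).
#'
#' @param x a single character string; terms are separated by `+`, each term
#'   is either `"<coef> <species>"` or `"<species>"` (coefficient 1).
#' @return named numeric vector of positive coefficients.
#' @examples
#' parse_side("2 A + 1 E")
#' parse_side("")
#' @export
parse_side <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "" || x == "0") return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
  terms <- terms[terms != ""]
  coefs <- numeric(length(terms))
  ids <- character(length(terms))
  for (i in seq_along(terms)) {
    parts <- strsplit(terms[[i]], "[[:space:]]+")[[1]]
    if (length(parts) == 1L) {
      coefs[i] <- 1
      ids[i] <- parts
    } else if (length(parts) == 2L && !is.na(suppressWarnings(as.numeric(parts[1])))) {
      coefs[i] <- as.numeric(parts[1])
      ids[i] <- parts[2]
    } else {
      abort(sprintf("cannot parse reaction side term '%s'", terms[[i]]))
    }
  }
  if (any(coefs <= 0)) abort("stoichiometric coefficients must be positive")
  # repeated species on one side accumulate
  tapply_sum <- tapply(coefs, ids, sum)
  out <- as.numeric(tapply_sum)
  names(out) <- names(tapply_sum)
  out[order(names(out))]
}

format_side <- function(comp) {
  if (length(comp) == 0L) return("0")
  comp <- comp[order(names(comp))]
  paste(ifelse(comp == 1, names(comp),
               paste(vapply(unname(comp), function(z) format(z, digits = 12), ""),
                     names(comp))),
        collapse = " + ")
}

# canonical identity key for a composition; exact for integers, 12 significant
# digits for fractional coefficients so deduplication is deterministic
complex_key <- function(comp) {
  if (length(comp) == 0L) return("")
  comp <- comp[order(names(comp))]
  paste(sprintf("%s:%s", names(comp),
                vapply(unname(comp), function(z) format(signif(z, 12), digits = 12), "")),
        collapse = ";")
}

as_composition <- function(x) {
  if (is.character(x)) parse_side(x) else {
    stopifnot(is.numeric(x))
    if (length(x) > 0 && is.null(names(x))) abort("compositions must be named")
    if (any(x <= 0)) abort("stoichiometric coefficients must be positive")
    x[order(names(x))]
  }
}

# ---- model construction --------------------------------------------------

#' Build a reaction network model on complexes
#'
#' Assembles the complex-graph representation of a reaction network from a
#' per-reaction table. The left- and right-hand sides of the reactions become
#' nodes ("complexes"); identical compositions are deduplicated, with indices
#' assigned in first-appearance order over the reaction list. The model
#' carries the species composition matrix `Y` (species x complexes), the
#' directed incidence matrix `A` (complexes x reactions, one -1 and one +1
#' per column) and hence the stoichiometric matrix `N = Y A`.
#'
#' @param reactions a data frame with columns `id`, `substrates`, `products`
#'   (character sides such as `"2 A + E"`, or list columns of named numeric
#'   coefficient vectors), and optionally `lb`, `ub` (flux bounds; defaults 0
#'   and `Inf`), `reversible` (logical, default `FALSE`).
#' @param species optional data frame with columns `id` and optionally
#'   `name`, `compartment`, supplying metadata for (a superset of) the
#'   species appearing in the reactions.
#' @param objective optional id of the objective (e.g. biomass) reaction.
#' @return a `network_model` object.
#' @details Reactions whose substrate side equals their product side (loops)
#'   do not contribute to the stoichiometric matrix and are rejected with a
#'   diagnostic. An empty side denotes the empty complex, a first-class node,
#'   so exchange reactions satisfy the one-(-1)-one-(+1) incidence contract.
#' @examples
#' rxn <- tibble::tibble(id = c("v1", "v2"),
#'                       substrates = c("A + B", "C"),
#'                       products   = c("C", ""),
#'                       lb = 0, ub = 10)
#' m <- build_complexes(rxn)
#' stoichiometric_matrix(m)
#' @export
build_complexes <- function(reactions, species = NULL, objective = NULL) {
  reactions <- as_tibble(reactions)
  stopifnot(all(c("id", "substrates", "products") %in% names(reactions)))
  if (anyDuplicated(reactions$id)) abort("reaction ids must be unique")
  n <- nrow(reactions)
  if (!"lb" %in% names(reactions)) reactions$lb <- 0
  if (!"ub" %in% names(reactions)) reactions$ub <- Inf
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  subs <- lapply(reactions$substrates, as_composition)
  prods <- lapply(reactions$products, as_composition)
  if (any(reactions$lb > reactions$ub)) {
    abort("reaction lower bounds must not exceed upper bounds")
  }

  keys_sub <- vapply(subs, complex_key, "")
  keys_prod <- vapply(prods, complex_key, "")
  loops <- keys_sub == keys_prod
  if (any(loops)) {
    abort(sprintf(
      "reaction(s) %s have identical substrate and product complexes (loops do not contribute to the stoichiometry)",
      paste(reactions$id[loops], collapse = ", ")))
  }

  # deduplicate complexes in first-appearance order
  all_keys <- character(0)
  all_comp <- list()
  idx_of <- function(key, comp) {
    j <- match(key, all_keys)
    if (is.na(j)) {
      all_keys[[length(all_keys) + 1L]] <<- key
      all_comp[[length(all_comp) + 1L]] <<- comp
      j <- length(all_keys)
    }
    j
  }
  sub_idx <- integer(n); prod_idx <- integer(n)
  for (i in seq_len(n)) {
    sub_idx[i] <- idx_of(keys_sub[i], subs[[i]])
    prod_idx[i] <- idx_of(keys_prod[i], prods[[i]])
  }

  sp_ids <- sort(unique(unlist(lapply(all_comp, names))))
  if (!is.null(species)) {
    species <- as_tibble(species)
    if (anyDuplicated(species$id)) abort("species ids must be unique")
    missing_sp <- setdiff(sp_ids, species$id)
    if (length(missing_sp)) {
      species <- bind_rows(species, tibble(id = missing_sp))
    }
    species <- species[species$id %in% sp_ids, , drop = FALSE]
    species <- species[order(match(species$id, sp_ids)), , drop = FALSE]
  } else {
    species <- tibble(id = sp_ids)
  }
  if (!"name" %in% names(species)) species$name <- species$id
  if (!"compartment" %in% names(species)) species$compartment <- NA_character_
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]

  Y <- composition_to_matrix(all_comp, species$id)
  complexes <- tibble(
    index = seq_along(all_comp),
    label = vapply(all_comp, format_side, ""),
    key = all_keys,
    composition = all_comp
  )
  rxn <- tibble(
    id = as.character(reactions$id),
    substrate = sub_idx,
    product = prod_idx,
    lb = as.numeric(reactions$lb),
    ub = as.numeric(reactions$ub),
    reversible = as.logical(reactions$reversible),
    provenance = if ("provenance" %in% names(reactions)) reactions$provenance
                 else as.list(as.character(reactions$id))
  )
  if (!is.null(objective) && !objective %in% rxn$id) {
    abort(sprintf("objective reaction '%s' not found", objective))
  }
  structure(
    list(species = species, complexes = complexes, reactions = rxn,
         Y = Y, objective = objective %||% NA_character_),
    class = "network_model")
}

composition_to_matrix <- function(comps, species_ids) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(comps)) {
    comp <- comps[[j]]
    if (length(comp) == 0L) next
    ii <- c(ii, match(names(comp), species_ids))
    jj <- c(jj, rep.int(j, length(comp)))
    xx <- c(xx, unname(comp))
  }
  sparseMatrix(i = ii, j = jj, x = xx,
               dims = c(length(species_ids), length(comps)),
               dimnames = list(species_ids, NULL))
}

#' Incidence matrix of the complex graph
#'
#' @param model a `network_model`.
#' @return sparse matrix `A` (complexes x reactions) with -1 at each
#'   reaction's substrate complex and +1 at its product complex; every column
#'   sums to zero.
#' @export
incidence_matrix <- function(model) {
  stopifnot(inherits(model, "network_model"))
  n <- nrow(model$reactions)
  sparseMatrix(
    i = c(model$reactions$substrate, model$reactions$product),
    j = rep(seq_len(n), 2L),
    x = c(rep(-1, n), rep(1, n)),
    dims = c(nrow(model$complexes), n),
    dimnames = list(NULL, model$reactions$id))
}

#' Species composition matrix of the complexes
#'
#' @param model a `network_model`.
#' @return sparse non-negative matrix `Y` (species x complexes); entry
#'   `y[i, j]` is the stoichiometry with which species `i` enters complex `j`.
#' @export
composition_matrix <- function(model) {
  stopifnot(inherits(model, "network_model"))
  model$Y
}

#' Stoichiometric matrix N = Y A
#'
#' @param model a `network_model`.
#' @return sparse stoichiometric matrix (species x reactions).
#' @export
stoichiometric_matrix <- function(model) {
  composition_matrix(model) %*% incidence_matrix(model)
}

# ---- reversibility -------------------------------------------------------

#' Split reversible reactions into irreversible pairs
#'
#' Replaces each reversible reaction by a forward/backward pair whose
#' incidence columns are negatives of each other (ids `<id>__fwd` and
#' `<id>__bwd`). Following the standard preprocessing convention for
#' balancing analysis, all lower bounds are set to zero and all upper bounds
#' to the maximum finite upper bound of the original model (1000 when no
#' finite upper bound exists).
#'
#' @param model a `network_model` whose reactions carry `reversible` flags.
#' @param mode `"keep"` honours the model's irreversibility flags;
#'   `"all-reversible"` treats every reaction as reversible, so `n` reactions
#'   become `2n`.
#' @return an irreversible `network_model`; `provenance` records the original
#'   reaction id and direction of each split half.
#' @export
split_reversible <- function(model, mode = c("keep", "all-reversible")) {
  stopifnot(inherits(model, "network_model"))
  mode <- match.arg(mode)
  rxn <- model$reactions
  rev <- if (mode == "all-reversible") rep(TRUE, nrow(rxn)) else rxn$reversible
  bad <- rxn$reversible & rxn$lb > 0
  if (any(bad)) {
    abort(sprintf("reversible reaction(s) %s have positive lower bounds, which contradicts reversibility",
                  paste(rxn$id[bad], collapse = ", ")))
  }
  ub_all <- rxn$ub
  ub_max <- if (any(is.finite(ub_all))) max(ub_all[is.finite(ub_all)]) else 1000
  if (any(!is.finite(ub_all))) {
    inform(sprintf("replacing infinite upper bounds by the model maximum %g", ub_max))
  }

  ids <- character(0); sub <- integer(0); prod <- integer(0)
  prov <- list()
  for (i in seq_len(nrow(rxn))) {
    if (rev[i]) {
      ids <- c(ids, paste0(rxn$id[i], "__fwd"), paste0(rxn$id[i], "__bwd"))
      sub <- c(sub, rxn$substrate[i], rxn$product[i])
      prod <- c(prod, rxn$product[i], rxn$substrate[i])
      prov <- c(prov, list(paste0(rxn$id[i], ":fwd")), list(paste0(rxn$id[i], ":bwd")))
    } else {
      ids <- c(ids, rxn$id[i])
      sub <- c(sub, rxn$substrate[i])
      prod <- c(prod, rxn$product[i])
      prov <- c(prov, rxn$provenance[i])
    }
  }
  new_rxn <- tibble(
    id = ids, substrate = sub, product = prod,
    lb = 0, ub = ub_max, reversible = FALSE, provenance = prov)
  out <- model
  out$reactions <- new_rxn
  if (!is.na(model$objective) && !(model$objective %in% ids)) {
    out$objective <- paste0(model$objective, "__fwd")
  }
  out
}

# ---- structural helpers --------------------------------------------------

in_reactions <- function(model, j) which(model$reactions$product == j)
out_reactions <- function(model, j) which(model$reactions$substrate == j)

#' Drop reactions and any orphaned complexes and species
#'
#' Removes the given reactions; complexes left with no incident reaction and
#' species appearing in no remaining complex are dropped, and complex indices
#' are compacted (preserving relative order).
#'
#' @param model a `network_model`.
#' @param ids reaction ids (character) or indices (integer) to remove.
#' @return the pruned `network_model`.
#' @export
drop_reactions <- function(model, ids) {
  stopifnot(inherits(model, "network_model"))
  idx <- if (is.character(ids)) match(ids, model$reactions$id) else as.integer(ids)
  if (anyNA(idx)) abort("unknown reaction id(s) in drop_reactions()")
  rxn <- model$reactions[-idx, , drop = FALSE]
  prune_model(model, rxn)
}

# rebuild a model around a replacement reaction table, dropping orphans
prune_model <- function(model, rxn) {
  used <- sort(unique(c(rxn$substrate, rxn$product)))
  remap <- match(seq_len(nrow(model$complexes)), used)
  rxn$substrate <- remap[rxn$substrate]
  rxn$product <- remap[rxn$product]
  complexes <- model$complexes[used, , drop = FALSE]
  complexes$index <- seq_len(nrow(complexes))
  Y <- model$Y[, used, drop = FALSE]
  keep_sp <- Matrix::rowSums(Y != 0) > 0
  Y <- Y[keep_sp, , drop = FALSE]
  species <- model$species[keep_sp, , drop = FALSE]
  out <- model
  out$species <- species
  out$complexes <- complexes
  out$reactions <- rxn
  out$Y <- Y
  if (!is.na(out$objective) && !(out$objective %in% rxn$id)) {
    out$objective <- NA_character_
  }
  out
}

#' Validate the structural invariants of a network model
#'
#' Checks that species and reaction ids are unique, complex compositions are
#' distinct and positive, every column of the incidence matrix has exactly one
#' -1 and one +1 in distinct rows, every species appears in at least one
#' complex, every complex in at least one reaction, bounds are ordered, and
#' `N = Y A` holds entry-wise.
#'
#' @param model a `network_model`.
#' @return `TRUE` invisibly; aborts with a diagnostic otherwise.
#' @export
validate_network_model <- function(model) {
  stopifnot(inherits(model, "network_model"))
  if (anyDuplicated(model$species$id)) abort("duplicate species ids")
  if (anyDuplicated(model$reactions$id)) abort("duplicate reaction ids")
  if (anyDuplicated(model$complexes$key)) abort("duplicate complex compositions")
  A <- incidence_matrix(model)
  if (!all(Matrix::colSums(A) == 0)) abort("incidence columns must sum to zero")
  if (!all(Matrix::colSums(A != 0) == 2 | Matrix::colSums(A != 0) == 0)) {
    abort("each incidence column must have exactly one -1 and one +1")
  }
  if (any(model$reactions$substrate == model$reactions$product)) {
    abort("loop reactions are not allowed")
  }
  if (any(model$Y@x < 0)) abort("Y must be non-negative")
  if (any(Matrix::rowSums(model$Y != 0) == 0)) abort("species appearing in no complex")
  incident <- sort(unique(c(model$reactions$substrate, model$reactions$product)))
  if (!identical(incident, seq_len(nrow(model$complexes)))) {
    abort("every complex must appear in at least one reaction")
  }
  if (any(model$reactions$lb > model$reactions$ub)) abort("lb > ub")
  N <- stoichiometric_matrix(model)
  N2 <- per_reaction_stoichiometry(model)
  if (max(abs(N - N2)) > 1e-12) abort("N = YA violated")
  invisible(TRUE)
}

# direct products-minus-substrates assembly, bypassing the Y/A factorization
per_reaction_stoichiometry <- function(model) {
  sp <- model$species$id
  n <- nrow(model$reactions)
  M <- Matrix(0, length(sp), n, sparse = TRUE,
              dimnames = list(sp, model$reactions$id))
  for (i in seq_len(n)) {
    s <- model$complexes$composition[[model$reactions$substrate[i]]]
    p <- model$complexes$composition[[model$reactions$product[i]]]
    if (length(s)) M[names(s), i] <- M[names(s), i] - unname(s)
    if (length(p)) M[names(p), i] <- M[names(p), i] + unname(p)
  }
  M
}

#' Expand a model back to a per-reaction substrate/product table
#'
#' Inverse of [build_complexes()] up to complex deduplication: each reaction
#' row regains its substrate- and product-side composition strings.
#'
#' @param model a `network_model`.
#' @return a tibble with columns `id`, `substrates`, `products`, `lb`, `ub`,
#'   `reversible`.
#' @export
reaction_table <- function(model) {
  stopifnot(inherits(model, "network_model"))
  tibble(
    id = model$reactions$id,
    substrates = model$complexes$label[model$reactions$substrate],
    products = model$complexes$label[model$reactions$product],
    lb = model$reactions$lb,
    ub = model$reactions$ub,
    reversible = model$reactions$reversible)
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d species, %d complexes, %d reactions\n",
              nrow(x$species), nrow(x$complexes), nrow(x$reactions)))
  if (!is.na(x$objective)) cat(sprintf("  objective: %s\n", x$objective))
  n_rev <- sum(x$reactions$reversible)
  if (n_rev > 0) cat(sprintf("  %d reversible reactions (pre-split)\n", n_rev))
  invisible(x)
}
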
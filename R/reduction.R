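# Removal of balanced complexes by graph rewiring.
#
# A balanced complex with l incoming and one outgoing reaction is removed by
# deleting the l+1 incident reactions and inserting l reactions from each
# incoming-neighbour complex to the outgoing neighbour; the outgoing flux is
# the sum of the incoming fluxes, so every steady-state flux distribution of
# the original network maps onto one of the reduced network. Under mass
# action a balanced complex with m outgoing reactions is removable for any m:
# the outgoing fluxes are fully coupled through the shared substrate monomial,
# and the m*l inserted reactions carry rescaled rate constants
# k_ip * k_jq / sum_q k_jq.

sym_k <- function(id) paste0("k(", id, ")")

#' Rescaled rate constant for a mass-action removal
#'
#' For an incoming reaction with constant `k_ip` and outgoing constants
#' `outgoing`, the inserted reaction towards the `q`-th outgoing neighbour
#' carries the constant `k_ip * outgoing[q] / sum(outgoing)`.
#'
#' @param k_ip positive rate constant of the incoming reaction.
#' @param outgoing vector of positive rate constants of the `m` outgoing
#'   reactions.
#' @param q index of the outgoing reaction served by the inserted reaction.
#' @return the rescaled rate constant.
#' @examples
#' rescale_rate_constant(2, c(1, 3), 1) # 0.5
#' rescale_rate_constant(2, c(1, 3), 2) # 1.5
#' @export
rescale_rate_constant <- function(k_ip, outgoing, q) {
  stopifnot(length(k_ip) == 1L, q >= 1L, q <= length(outgoing))
  if (any(outgoing <= 0) || k_ip <= 0) rlang::abort("rate constants must be positive")
  s <- sum(outgoing)
  if (s == 0) rlang::abort("sum of outgoing rate constants is zero")
  k_ip * outgoing[q] / s
}

new_substitution <- function(kind, removed, coef, symbol, flux_map, complex_label, round = NA_integer_) {
  list(kind = kind, removed = removed,
       expression = tibble::tibble(coef = coef, symbol = symbol),
       flux_map = flux_map, complex = complex_label, round = round)
}

#' Remove a balanced complex with a single outgoing reaction
#'
#' Deletes the `l + 1` reactions incident on complex `j` and inserts `l`
#' reactions connecting each incoming-neighbour complex to the outgoing
#' neighbour. Inserted reactions keep the id, bounds and flux value of the
#' incoming reaction they replace (with the upper bound additionally capped
#' by the outgoing reaction's when `l = 1`); self-loop insertions are
#' discarded since they do not contribute to the stoichiometry. The flux
#' substitution `v_out = sum of incoming fluxes` is recorded.
#'
#' @param model a split, blocked-free `network_model`; complex `j` is assumed
#'   balanced (the caller certifies this, e.g. [reduce_network()]).
#' @param j index of the complex to remove.
#' @return list with `model` (reduced) and `substitution` (removal record
#'   with the flux map).
#' @export
remove_single_outgoing <- function(model, j) {
  ins <- in_reactions(model, j)
  outs <- out_reactions(model, j)
  if (length(outs) != 1L) {
    rlang::abort(sprintf("complex %d has %d outgoing reactions; single-outgoing removal requires exactly 1",
                         j, length(outs)))
  }
  if (length(ins) < 1L) rlang::abort("complex has no incoming reaction")
  rxn <- model$reactions
  out_id <- rxn$id[outs]
  target <- rxn$product[outs]
  l <- length(ins)

  keep <- rxn[-c(ins, outs), , drop = FALSE]
  new_rows <- list()
  map_new <- character(0); map_src <- character(0); map_share <- numeric(0)
  for (p in ins) {
    s_p <- rxn$substrate[p]
    if (s_p == target) next  # loop insertion discarded
    ub <- if (l == 1L) min(rxn$ub[p], rxn$ub[outs]) else rxn$ub[p]
    new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
      id = rxn$id[p], substrate = s_p, product = target,
      lb = rxn$lb[p], ub = ub, reversible = FALSE,
      provenance = list(unique(c(rxn$provenance[[p]], rxn$provenance[[outs]]))))
    map_new <- c(map_new, rxn$id[p])
    map_src <- c(map_src, rxn$id[p])
    map_share <- c(map_share, 1)
  }
  new_tbl <- dplyr::bind_rows(keep, dplyr::bind_rows(new_rows))
  sub <- new_substitution(
    kind = "flux", removed = out_id,
    coef = rep(1, l), symbol = rxn$id[ins],
    flux_map = list(deleted = c(rxn$id[ins], out_id),
                    inserted = tibble::tibble(new_id = map_new, source_id = map_src,
                                              share = map_share)),
    complex_label = model$complexes$label[j])
  list(model = prune_model(model, new_tbl), substitution = sub)
}

#' Remove a balanced complex under mass-action kinetics
#'
#' Deletes the `l + m` reactions incident on complex `j` and inserts `m * l`
#' reactions, one per (incoming, outgoing) neighbour pair, with rate
#' constants rescaled by [rescale_rate_constant()]. Loop insertions are
#' discarded and parallel duplicates merged by summing their constants (which
#' preserves the mass-action dynamics exactly). The monomial substitution
#' `x^y = sum_p (k_ip / sum_q k_jq) x^y(ip)` is recorded, so the steady-state
#' concentration monomial of the removed complex stays expressible in the
#' surviving species.
#'
#' @param model a split, blocked-free `network_model`; complex `j` is assumed
#'   balanced.
#' @param kinetics named numeric vector of rate constants, or `NULL` for
#'   symbolic constants (recorded as expression strings built from
#'   `k(<reaction id>)` tokens).
#' @param j index of the complex to remove.
#' @return list with `model`, `kinetics` (rescaled; character expressions in
#'   symbolic mode) and `substitution`.
#' @export
remove_mass_action <- function(model, kinetics, j) {
  ins <- in_reactions(model, j)
  outs <- out_reactions(model, j)
  if (length(ins) < 1L || length(outs) < 1L) {
    rlang::abort("mass-action removal requires at least one incoming and one outgoing reaction")
  }
  rxn <- model$reactions
  symbolic <- is.null(kinetics) || is.character(kinetics)
  if (symbolic) {
    base <- if (is.null(kinetics)) stats::setNames(sym_k(rxn$id), rxn$id) else kinetics
    miss <- setdiff(rxn$id[c(ins, outs)], names(base))
    if (length(miss)) rlang::abort(sprintf("kinetics missing for reaction(s): %s", paste(miss, collapse = ", ")))
    kin <- base
  } else {
    kinetics_for(model, kinetics, rxn$id[c(ins, outs)])
    kin <- kinetics
  }
  k_out <- kin[rxn$id[outs]]
  if (symbolic) {
    denom <- paste(k_out, collapse = " + ")
    shares <- stats::setNames(paste0("(", k_out, ")/(", denom, ")"), rxn$id[outs])
  } else {
    shares <- stats::setNames(unname(k_out) / sum(k_out), rxn$id[outs])
  }

  keep <- rxn[-c(ins, outs), , drop = FALSE]
  kin_new <- kin[setdiff(names(kin), rxn$id[c(ins, outs)])]
  new_rows <- list()
  map <- list()
  for (p in ins) {
    for (q in outs) {
      s_p <- rxn$substrate[p]; t_q <- rxn$product[q]
      if (s_p == t_q) next  # loop insertion discarded
      id_new <- paste0(rxn$id[p], "__", rxn$id[q])
      if (symbolic) {
        k_new <- paste0("(", kin[[rxn$id[p]]], ")*(", kin[[rxn$id[q]]], ")/(",
                        paste(k_out, collapse = " + "), ")")
        share_num <- NA_real_
        lb <- 0; ub <- rxn$ub[p]
      } else {
        k_new <- rescale_rate_constant(kin[[rxn$id[p]]], unname(k_out), match(q, outs))
        share_num <- unname(shares[rxn$id[q]])
        lb <- rxn$lb[p] * share_num; ub <- rxn$ub[p] * share_num
      }
      new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
        id = id_new, substrate = s_p, product = t_q, lb = lb, ub = ub,
        reversible = FALSE,
        provenance = list(unique(c(rxn$provenance[[p]], rxn$provenance[[q]]))),
        k = list(k_new))
      map[[length(map) + 1L]] <- tibble::tibble(
        new_id = id_new, source_id = rxn$id[p], share = share_num)
    }
  }
  new_tbl <- dplyr::bind_rows(new_rows)
  map_tbl <- dplyr::bind_rows(map)

  # merge parallel duplicates (among insertions and with surviving reactions)
  if (nrow(new_tbl)) {
    for (i in seq_len(nrow(new_tbl))) {
      if (is.na(new_tbl$id[i])) next
      # merge with an earlier insertion on the same edge
      dup <- which(!is.na(new_tbl$id) & seq_len(nrow(new_tbl)) < i &
                     new_tbl$substrate == new_tbl$substrate[i] &
                     new_tbl$product == new_tbl$product[i])
      target_row <- NULL
      if (length(dup)) target_row <- dup[1]
      if (is.null(target_row)) {
        ex <- which(keep$substrate == new_tbl$substrate[i] & keep$product == new_tbl$product[i])
        if (length(ex)) {
          ex <- ex[1]
          kin_new[[keep$id[ex]]] <- merge_constants(kin_new[[keep$id[ex]]], new_tbl$k[[i]], symbolic)
          keep$lb[ex] <- keep$lb[ex] + new_tbl$lb[i]
          keep$ub[ex] <- keep$ub[ex] + new_tbl$ub[i]
          keep$provenance[[ex]] <- unique(c(keep$provenance[[ex]], new_tbl$provenance[[i]]))
          map_tbl$new_id[map_tbl$new_id == new_tbl$id[i]] <- keep$id[ex]
          new_tbl$id[i] <- NA_character_
          next
        }
        next
      }
      new_tbl$k[[target_row]] <- merge_constants(new_tbl$k[[target_row]], new_tbl$k[[i]], symbolic)
      new_tbl$lb[target_row] <- new_tbl$lb[target_row] + new_tbl$lb[i]
      new_tbl$ub[target_row] <- new_tbl$ub[target_row] + new_tbl$ub[i]
      new_tbl$provenance[[target_row]] <- unique(c(new_tbl$provenance[[target_row]],
                                                   new_tbl$provenance[[i]]))
      map_tbl$new_id[map_tbl$new_id == new_tbl$id[i]] <- new_tbl$id[target_row]
      new_tbl$id[i] <- NA_character_
    }
    new_tbl <- new_tbl[!is.na(new_tbl$id), , drop = FALSE]
  }
  if (nrow(new_tbl)) {
    for (i in seq_len(nrow(new_tbl))) kin_new[[new_tbl$id[i]]] <- new_tbl$k[[i]]
    new_tbl$k <- NULL
  }

  # monomial substitution: x^y(j) = sum_p (k_ip / sum_q k_jq) x^y(s_p)
  in_ids <- rxn$id[ins]
  if (symbolic) {
    denom <- paste(k_out, collapse = " + ")
    coefs <- paste0("(", vapply(in_ids, function(id) kin[[id]], ""), ")/(", denom, ")")
  } else {
    coefs <- unname(kin[in_ids]) / sum(k_out)
  }
  sub <- new_substitution(
    kind = "monomial",
    removed = model$complexes$label[j],
    coef = coefs,
    symbol = model$complexes$label[rxn$substrate[ins]],
    flux_map = list(deleted = rxn$id[c(ins, outs)], inserted = map_tbl),
    complex_label = model$complexes$label[j])
  reduced <- prune_model(model, dplyr::bind_rows(keep, new_tbl))
  kin_new <- kin_new[intersect(names(kin_new), reduced$reactions$id)]
  list(model = reduced,
       kinetics = if (symbolic) unlist(kin_new) else unlist(kin_new),
       substitution = sub)
}

merge_constants <- function(a, b, symbolic) {
  if (symbolic) paste0("(", a, ") + (", b, ")") else a + b
}

#' Iterative reduction by removal of balanced complexes
#'
#' Alternates identification and removal of balanced complexes until no
#' further complex is removable. Under arbitrary kinetics only balanced
#' complexes with a single outgoing reaction are removed (optionally also
#' multi-outgoing complexes whose outgoing reactions are fully coupled);
#' under mass action any balanced complex with incoming and outgoing
#' reactions is removable, with rate constants rescaled at every step.
#' Within a round trivially balanced complexes are processed first, then the
#' rest in ascending index order; every non-trivially-balanced candidate is
#' re-certified by its two LPs on the current model immediately before
#' removal. Complexes containing a protected species are never removed.
#'
#' @param model a split, blocked-free `network_model`.
#' @param kinetics named numeric rate constants (required for numeric
#'   mass-action rescaling; `NULL` gives symbolic constants in mass-action
#'   mode and is ignored in arbitrary mode).
#' @param mode `"arbitrary"` (single-outgoing removals, flux substitution)
#'   or `"mass_action"` (any balanced complex, monomial substitution).
#' @param protect character vector of species ids that must survive: any
#'   complex containing one of them is kept (used to preserve e.g. biomass
#'   precursors).
#' @param keep_reactions reaction ids that must survive verbatim: the
#'   complexes incident on them are never removed. The model's objective
#'   reaction is always kept when present, so growth predictions remain
#'   comparable between the original and reduced model.
#' @param constraints optional extra linear constraints (see [flux_space()])
#'   re-applied to every round's flux space.
#' @param tol balancedness tolerance.
#' @param allow_coupled experimental: in arbitrary mode, also remove balanced
#'   complexes whose several outgoing reactions are pairwise fully coupled,
#'   splitting the incoming flux by the coupling ratios.
#' @param max_rounds safety cap on identification rounds.
#' @return a `reduction_result` with the reduced model, rescaled kinetics,
#'   removal records (flux/monomial substitutions), per-round log and the
#'   removed complexes and species.
#' @export
reduce_network <- function(model, kinetics = NULL,
                           mode = c("arbitrary", "mass_action"),
                           protect = character(), constraints = NULL,
                           keep_reactions = character(),
                           tol = 1e-9, allow_coupled = FALSE,
                           max_rounds = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "network_model"))
  if (!is.na(model$objective)) keep_reactions <- union(keep_reactions, model$objective)
  current <- model
  kin <- if (mode == "mass_action") kinetics else NULL
  if (mode == "mass_action" && is.numeric(kinetics)) {
    kinetics_for(model, kinetics, model$reactions$id)
  }
  subs <- list()
  rounds_log <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds) break
    if (nrow(current$reactions) == 0L) { round <- round - 1L; break }
    fs <- flux_space(current, extra = constraints)
    rep <- identify_balanced(current, fs, tol = tol)
    protected <- union(protected_complexes(current, protect),
                       incident_complexes(current, keep_reactions))
    cand <- rep[rep$balanced & !(rep$complex %in% protected), , drop = FALSE]
    if (mode == "arbitrary" && !allow_coupled) {
      cand <- cand[cand$n_out == 1L, , drop = FALSE]
    }
    cand <- cand[order(!cand$trivially_balanced, cand$complex), , drop = FALSE]
    if (nrow(cand) == 0L) { round <- round - 1L; break }

    removed_this_round <- 0L
    sp_before <- nrow(current$species)
    rx_before <- nrow(current$reactions)
    for (key in current$complexes$key[cand$complex]) {
      j <- match(key, current$complexes$key)
      if (is.na(j)) next  # complex vanished in an earlier removal this round
      n_out <- length(out_reactions(current, j))
      n_in <- length(in_reactions(current, j))
      if (n_in < 1L || n_out < 1L) next
      if (mode == "arbitrary" && !allow_coupled && n_out != 1L) next
      if (j %in% union(protected_complexes(current, protect),
                       incident_complexes(current, keep_reactions))) next
      trivial_now <- j %in% classify_trivially_balanced(current)
      if (!trivial_now) {
        fs_now <- flux_space(current, extra = constraints)
        b <- net_flux_bounds(current, fs_now, j)
        if (abs(b[1]) > tol || abs(b[2]) > tol) next  # no longer balanced
      }
      step <- if (mode == "mass_action") {
        remove_mass_action(current, kin, j)
      } else if (n_out == 1L) {
        remove_single_outgoing(current, j)
      } else {
        step_c <- remove_coupled_outgoing(current, j, constraints)
        if (is.null(step_c)) next
        step_c
      }
      current <- step$model
      if (!is.null(step$kinetics)) kin <- step$kinetics
      step$substitution$round <- round
      subs[[length(subs) + 1L]] <- step$substitution
      removed_this_round <- removed_this_round + 1L
    }
    rounds_log[[round]] <- tibble::tibble(
      round = round,
      complexes_removed = removed_this_round,
      species_removed = sp_before - nrow(current$species),
      reactions_before = rx_before,
      reactions_after = nrow(current$reactions))
    if (removed_this_round == 0L) { round <- round - 1L; break }
  }

  removed_cx <- setdiff(model$complexes$key, current$complexes$key)
  structure(
    list(original = model,
         model = current,
         kinetics = kin,
         substitutions = subs,
         rounds = dplyr::bind_rows(rounds_log),
         removed_complexes = model$complexes$label[match(removed_cx, model$complexes$key)],
         removed_species = setdiff(model$species$id, current$species$id),
         mode = mode,
         protect = protect),
    class = "reduction_result")
}

incident_complexes <- function(model, reaction_ids) {
  if (!length(reaction_ids)) return(integer(0))
  i <- which(model$reactions$id %in% reaction_ids)
  unique(c(model$reactions$substrate[i], model$reactions$product[i]))
}

protected_complexes <- function(model, protect) {
  if (!length(protect)) return(integer(0))
  sp <- intersect(protect, model$species$id)
  if (!length(sp)) return(integer(0))
  rows <- match(sp, model$species$id)
  which(Matrix::colSums(model$Y[rows, , drop = FALSE] != 0) > 0)
}

# experimental: remove a balanced complex whose outgoing reactions are all
# fully coupled, splitting incoming flux by the coupling ratios
remove_coupled_outgoing <- function(model, j, constraints = NULL) {
  fs <- flux_space(model, extra = constraints)
  outs <- out_reactions(model, j)
  ids <- model$reactions$id[outs]
  ratios <- rep(NA_real_, length(ids))
  ratios[1] <- 1
  for (q in seq_along(ids)[-1]) {
    fc <- fully_coupled(model, fs, ids[q], ids[1])
    if (!isTRUE(fc$coupled)) return(NULL)
    ratios[q] <- fc$ratio
  }
  shares <- ratios / sum(ratios)
  kin_fake <- stats::setNames(rep(1, nrow(model$reactions)), model$reactions$id)
  kin_fake[ids] <- shares
  step <- remove_mass_action(model, kin_fake, j)
  step$kinetics <- NULL
  step$substitution$kind <- "flux"
  step
}

#' Apply a reduction's flux substitution map to a flux vector
#'
#' Maps a steady-state flux distribution of the original network onto the
#' reduced network: fluxes of deleted reactions are dropped and each inserted
#' reaction receives its recorded share of the incoming flux it replaces
#' (share 1 in the single-outgoing case).
#'
#' @param result a `reduction_result`.
#' @param v named flux vector over the original model's reactions.
#' @return named flux vector over the reduced model's reactions.
#' @export
apply_flux_map <- function(result, v) {
  stopifnot(inherits(result, "reduction_result"))
  stopifnot(!is.null(names(v)))
  for (sub in result$substitutions) {
    fm <- sub$flux_map
    out <- v[setdiff(names(v), fm$deleted)]
    ins <- fm$inserted
    if (nrow(ins)) {
      if (anyNA(ins$share)) rlang::abort("flux map has symbolic shares; numeric kinetics required")
      for (i in seq_len(nrow(ins))) {
        add <- ins$share[i] * v[[ins$source_id[i]]]
        out[[ins$new_id[i]]] <- (if (ins$new_id[i] %in% names(out)) out[[ins$new_id[i]]] else 0) + add
      }
    }
    v <- out
  }
  v[result$model$reactions$id]
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> mode = %s\n", x$mode))
  cat(sprintf("  species:   %d -> %d\n", nrow(x$original$species), nrow(x$model$species)))
  cat(sprintf("  complexes: %d -> %d\n", nrow(x$original$complexes), nrow(x$model$complexes)))
  cat(sprintf("  reactions: %d -> %d\n", nrow(x$original$reactions), nrow(x$model$reactions)))
  if (nrow(x$rounds)) cat(sprintf("  rounds: %d, removed complexes: %s\n",
                                  max(x$rounds$round),
                                  paste(x$removed_complexes, collapse = ", ")))
  invisible(x)
}
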
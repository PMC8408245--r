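# Identification and classification of balanced complexes.
#
# A complex is balanced in a flux space S when the net flux around it,
# [A v]_i (incoming minus outgoing), is zero for every v in S. This is
# certified by two LPs per complex: min and max of [A v]_i subject to
# N v = 0 and the bounds.

#' Net-flux bounds of one complex
#'
#' Minimum and maximum of the signed flux sum around complex `j` (row `j` of
#' the incidence matrix dotted with `v`: incoming +1, outgoing -1) over the
#' flux space.
#'
#' @param model a split, blocked-free `network_model`.
#' @param fspace a `flux_space` for the model.
#' @param j complex index.
#' @return numeric vector `c(min, max)`.
#' @export
net_flux_bounds <- function(model, fspace, j) {
  obj <- incidence_row(model, j)
  lo <- solve_lp(fspace, obj, maximize = FALSE)
  hi <- solve_lp(fspace, obj, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal") {
    rlang::abort(sprintf("LP failed for complex %d (status %s/%s)", j, lo$status, hi$status))
  }
  c(lo$value, hi$value)
}

incidence_row <- function(model, j) {
  obj <- numeric(nrow(model$reactions))
  obj[model$reactions$product == j] <- 1
  obj[model$reactions$substrate == j] <- obj[model$reactions$substrate == j] - 1
  obj
}

#' Trivially balanced complexes
#'
#' A complex is trivially balanced when it has at least one incoming and one
#' outgoing reaction and contains a species occurring in no other complex:
#' the steady-state balance of that species forces the net flux around the
#' complex to zero for every steady state, without solving any LP.
#'
#' @param model a split, blocked-free `network_model`.
#' @return integer vector of complex indices.
#' @export
classify_trivially_balanced <- function(model) {
  stopifnot(inherits(model, "network_model"))
  occurs <- Matrix::rowSums(model$Y != 0)  # complexes per species
  unique_sp <- which(occurs == 1)
  if (!length(unique_sp)) return(integer(0))
  cand <- sort(unique(unlist(lapply(unique_sp, function(s) which(model$Y[s, ] != 0)))))
  has_in <- tabulate(model$reactions$product, nbins = nrow(model$complexes)) > 0
  has_out <- tabulate(model$reactions$substrate, nbins = nrow(model$complexes)) > 0
  cand[has_in[cand] & has_out[cand]]
}

#' Identify balanced complexes
#'
#' Runs the paired net-flux LPs for every complex of the model over the given
#' flux space and classifies the complexes. Sink and source complexes cannot
#' be balanced in a blocked-free model and are screened out without LPs
#' (unless `screen = FALSE`); trivially balanced complexes are flagged
#' structurally and their net-flux bounds set to zero, which the LPs confirm
#' when `verify_trivial = TRUE`.
#'
#' @param model a split, blocked-free `network_model`.
#' @param fspace a `flux_space`; defaults to the model's.
#' @param tol balancedness tolerance: balanced means `|min|` and `|max|` of
#'   the net flux are both below `tol`.
#' @param screen skip LPs for sink/source complexes.
#' @param verify_trivial solve the LPs for trivially balanced complexes too.
#' @return a tibble (one row per complex) with columns `complex`, `label`,
#'   `n_in`, `n_out`, `net_min`, `net_max`, `balanced`,
#'   `trivially_balanced`, `non_trivially_balanced`, `sink`, `source`,
#'   `single_outgoing`.
#' @export
identify_balanced <- function(model, fspace = flux_space(model), tol = 1e-9,
                              screen = TRUE, verify_trivial = FALSE) {
  stopifnot(tol > 0)
  nc <- nrow(model$complexes)
  n_in <- tabulate(model$reactions$product, nbins = nc)
  n_out <- tabulate(model$reactions$substrate, nbins = nc)
  sink <- n_in > 0 & n_out == 0
  source <- n_out > 0 & n_in == 0
  trivial <- rep(FALSE, nc)
  trivial[classify_trivially_balanced(model)] <- TRUE

  net_min <- rep(NA_real_, nc)
  net_max <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    if (screen && (sink[j] || source[j])) next
    if (trivial[j] && !verify_trivial) {
      net_min[j] <- 0; net_max[j] <- 0
      next
    }
    b <- net_flux_bounds(model, fspace, j)
    net_min[j] <- b[1]; net_max[j] <- b[2]
  }
  balanced <- !is.na(net_min) & abs(net_min) <= tol & abs(net_max) <= tol
  balanced[sink | source] <- FALSE
  tibble::tibble(
    complex = seq_len(nc),
    label = model$complexes$label,
    n_in = n_in, n_out = n_out,
    net_min = net_min, net_max = net_max,
    balanced = balanced,
    trivially_balanced = trivial,
    non_trivially_balanced = balanced & !trivial,
    sink = sink, source = source,
    single_outgoing = balanced & n_out == 1L)
}

#' Flux coupling of a reaction pair
#'
#' Two unblocked reactions are fully coupled when their flux ratio is one
#' fixed constant across all steady states. Following standard flux-coupling
#' practice the test runs on the homogenized flux cone (bounds relaxed to
#' `[0, Inf)`): minimize and maximize `v_a` subject to `N v = 0`, `v >= 0`,
#' `v_b = 1`; the reactions are coupled when the two optima coincide.
#'
#' @param model a split `network_model`.
#' @param fspace a `flux_space` (only its stoichiometry is used).
#' @param a,b reaction ids.
#' @param tol relative tolerance for deciding the two optima coincide.
#' @return list with `coupled` (logical) and `ratio` (`v_a / v_b`, or `NA`
#'   when not coupled or when `v_b` is forced to zero in the cone, which
#'   signals a blocked pairing).
#' @export
fully_coupled <- function(model, fspace = flux_space(model), a, b, tol = 1e-8) {
  ids <- fspace$reaction_ids
  stopifnot(a %in% ids, b %in% ids)
  big <- 1e6
  cone <- fspace
  cone$vmin <- rep(0, length(ids))
  cone$vmax <- rep(big, length(ids))
  cone$extra <- tibble::tibble(coef = list(stats::setNames(1, b)), rel = "=", rhs = 1)
  lo <- solve_lp(cone, stats::setNames(1, a), maximize = FALSE)
  if (lo$status != "optimal") {
    return(list(coupled = FALSE, ratio = NA_real_, status = "b_blocked"))
  }
  hi <- solve_lp(cone, stats::setNames(1, a), maximize = TRUE)
  if (hi$value >= big - 1) {
    return(list(coupled = FALSE, ratio = NA_real_, status = "unbounded"))
  }
  coupled <- (hi$value - lo$value) <= tol * max(1, abs(hi$value))
  list(coupled = coupled,
       ratio = if (coupled) (hi$value + lo$value) / 2 else NA_real_,
       status = "ok")
}
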
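# Plain-text tabular I/O: reaction tables, kinetics tables and reports.
#
# The reaction-table format is a TSV with columns reaction_id,
# substrate_side, product_side, lb, ub, reversible {0,1} and optionally
# rate_constant; sides are written like "2 A + 1 E" and an empty side
# denotes the empty complex. Floats are serialized with 17 significant
# digits so values round-trip exactly.

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Read a reaction table
#'
#' @param path TSV file with columns `reaction_id`, `substrate_side`,
#'   `product_side`, `lb`, `ub`, `reversible`, and optionally
#'   `rate_constant`.
#' @return a `network_model`; when the table carries rate constants they are
#'   attached as the `"kinetics"` attribute.
#' @export
read_reaction_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", colClasses = "character")
  need <- c("reaction_id", "substrate_side", "product_side", "lb", "ub", "reversible")
  if (!all(need %in% names(df))) {
    rlang::abort(sprintf("reaction table must have columns: %s", paste(need, collapse = ", ")))
  }
  df$substrate_side[is.na(df$substrate_side)] <- ""
  df$product_side[is.na(df$product_side)] <- ""
  rxn <- tibble::tibble(
    id = df$reaction_id,
    substrates = df$substrate_side,
    products = df$product_side,
    lb = as.numeric(df$lb),
    ub = as.numeric(df$ub),
    reversible = as.integer(df$reversible) == 1L)
  model <- build_complexes(rxn)
  if ("rate_constant" %in% names(df) && any(!is.na(df$rate_constant) & df$rate_constant != "")) {
    k <- as.numeric(df$rate_constant)
    attr(model, "kinetics") <- stats::setNames(k, df$reaction_id)[!is.na(k)]
  }
  model
}

#' Write a reaction table
#'
#' @param model a `network_model`.
#' @param path output TSV path.
#' @param kinetics optional named numeric rate constants to include as a
#'   `rate_constant` column.
#' @export
write_reaction_table <- function(model, path, kinetics = NULL) {
  tab <- reaction_table(model)
  sides <- function(lbl) ifelse(lbl == "0", "", lbl)
  df <- data.frame(
    reaction_id = tab$id,
    substrate_side = sides(tab$substrates),
    product_side = sides(tab$products),
    lb = fmt17(tab$lb),
    ub = ifelse(is.finite(tab$ub), fmt17(tab$ub), "Inf"),
    reversible = as.integer(tab$reversible),
    stringsAsFactors = FALSE)
  if (!is.null(kinetics)) {
    df$rate_constant <- ifelse(tab$id %in% names(kinetics),
                               fmt17(unname(kinetics[tab$id])), "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rate-constant table
#'
#' @param path TSV with columns `reaction_id` and `k`.
#' @param model optional `network_model`; when given, every id in the table
#'   must match a model reaction (split-pair ids `<id>__fwd` / `<id>__bwd`
#'   resolve as written) and unmatched ids raise an error listing them.
#' @return named numeric vector of positive rate constants.
#' @export
read_kinetics <- function(path, model = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "k") %in% names(df))) {
    rlang::abort("kinetics table must have columns reaction_id, k")
  }
  k <- stats::setNames(as.numeric(df$k), df$reaction_id)
  if (any(is.na(k)) || any(k <= 0)) {
    rlang::abort("rate constants must be positive numbers")
  }
  if (anyDuplicated(names(k))) rlang::abort("duplicate reaction ids in kinetics table")
  if (!is.null(model)) {
    miss <- setdiff(names(k), model$reactions$id)
    if (length(miss)) {
      rlang::abort(sprintf("kinetics for unknown reaction(s): %s", paste(miss, collapse = ", ")))
    }
  }
  k
}

#' Write a rate-constant table
#'
#' @param kinetics named numeric vector.
#' @param path output TSV path.
#' @export
write_kinetics <- function(kinetics, path) {
  utils::write.table(
    data.frame(reaction_id = names(kinetics), k = fmt17(unname(kinetics))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a balanced-complex report
#'
#' @param report tibble from [identify_balanced()].
#' @param path output TSV path.
#' @export
write_balanced_report <- function(report, path) {
  df <- as.data.frame(report)
  for (col in c("net_min", "net_max")) df[[col]] <- ifelse(is.na(df[[col]]), "NA", fmt17(df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write substitution maps and run metadata as JSON
#'
#' @param result a `reduction_result`.
#' @param path output JSON path.
#' @param meta optional named list of run metadata to embed.
#' @export
write_substitutions <- function(result, path, meta = NULL) {
  subs <- lapply(result$substitutions, function(s) {
    list(kind = s$kind, round = s$round, complex = s$complex,
         removed = s$removed,
         expression = list(coef = s$expression$coef, symbol = s$expression$symbol),
         deleted = s$flux_map$deleted,
         inserted = s$flux_map$inserted)
  })
  payload <- list(meta = meta, summary = as.list(glance(result)), substitutions = subs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
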
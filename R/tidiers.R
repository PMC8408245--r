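# broom-style accessors and plots for reduction results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the substitution records of a reduction
#'
#' @param x a `reduction_result`.
#' @param ... unused.
#' @return tibble with one row per removal: `round`, `kind` (`flux` or
#'   `monomial`), `complex` (removed complex label), `removed` (the
#'   substituted reaction flux or complex monomial) and `expression` (its
#'   replacement as a readable linear combination).
#' @export
tidy.reduction_result <- function(x, ...) {
  if (!length(x$substitutions)) {
    return(tibble::tibble(round = integer(0), kind = character(0),
                          complex = character(0), removed = character(0),
                          expression = character(0)))
  }
  dplyr::bind_rows(lapply(x$substitutions, function(s) {
    expr <- paste(
      vapply(seq_len(nrow(s$expression)), function(i) {
        cf <- s$expression$coef[i]
        sym <- s$expression$symbol[i]
        sym <- if (s$kind == "monomial") paste0("x^{", sym, "}") else paste0("v[", sym, "]")
        if (is.numeric(cf) && isTRUE(all.equal(unname(cf), 1))) sym
        else paste0("(", format(cf, digits = 6), ")*", sym)
      }, ""),
      collapse = " + ")
    removed <- if (s$kind == "monomial") paste0("x^{", s$removed, "}") else paste0("v[", s$removed, "]")
    tibble::tibble(round = s$round, kind = s$kind, complex = s$complex,
                   removed = removed, expression = expr)
  }))
}

#' One-row summary of a reduction
#'
#' @param x a `reduction_result`.
#' @param ... unused.
#' @return tibble with species/complex/reaction counts before and after,
#'   number of rounds and removals.
#' @export
glance.reduction_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    species_original = nrow(x$original$species),
    species_reduced = nrow(x$model$species),
    complexes_original = nrow(x$original$complexes),
    complexes_reduced = nrow(x$model$complexes),
    reactions_original = nrow(x$original$reactions),
    reactions_reduced = nrow(x$model$reactions),
    rounds = if (nrow(x$rounds)) max(x$rounds$round) else 0L,
    complexes_removed = length(x$removed_complexes),
    species_removed = length(x$removed_species),
    percent_species_removed =
      100 * length(x$removed_species) / max(1L, nrow(x$original$species)))
}

#' Plot the size of a model before and after reduction
#'
#' @param object a `reduction_result`.
#' @param ... unused.
#' @return a ggplot barchart of species, complex and reaction counts.
#' @export
autoplot.reduction_result <- function(object, ...) {
  g <- glance(object)
  df <- tidyr::pivot_longer(
    g[, c("species_original", "species_reduced", "complexes_original",
          "complexes_reduced", "reactions_original", "reactions_reduced")],
    cols = dplyr::everything(),
    names_to = c("entity", "model"), names_sep = "_", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entity, y = .data$count, fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL,
                  title = "Model size before and after reduction") +
    ggplot2::theme_minimal()
}

#' Plot the net-flux ranges of a balanced-complex report
#'
#' @param report output of [identify_balanced()].
#' @return a ggplot range plot of per-complex net-flux bounds, coloured by
#'   balancedness.
#' @export
plot_balanced_report <- function(report) {
  df <- report[!is.na(report$net_min), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$complex),
                                   ymin = .data$net_min, ymax = .data$net_max,
                                   colour = .data$balanced)) +
    ggplot2::geom_linerange(linewidth = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "complex", y = "net flux range over the flux space",
                  colour = "balanced") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
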
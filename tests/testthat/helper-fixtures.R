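# shared fixture builders (all fixtures are generated in code)

# open linear chain 0 -> S1 -> ... -> Sn -> 0
chain_model <- function(n = 2, ub = 10) {
  sp <- paste0("S", seq_len(n))
  rxn <- tibble::tibble(
    id = paste0("r", seq_len(n + 1)),
    substrates = c("", sp),
    products = c(sp, ""),
    lb = 0, ub = ub)
  build_complexes(rxn)
}

# a blocked-free open model whose balanced set is empty:
# 0 -> A (sink complex A), 2A -> 0 (source complex 2A)
no_balanced_model <- function() {
  rxn <- tibble::tibble(
    id = c("in_A", "out_2A"),
    substrates = c("", "2 A"),
    products = c("A", ""),
    lb = 0, ub = 10)
  build_complexes(rxn)
}

# canonical topology signature for comparing models up to complex relabeling
edge_signature <- function(model) {
  paste(sort(paste(model$complexes$key[model$reactions$substrate],
                   model$complexes$key[model$reactions$product], sep = " -> ")),
        collapse = " ; ")
}

balanced_labels <- function(model, ...) {
  rep <- identify_balanced(model, ...)
  sort(rep$label[rep$balanced])
}

small_spec <- function(seed) {
  planted_network_spec(n_species = 5, n_complexes = 4, n_reactions = 8,
                       n_planted_trivial = 1, seed = seed)
}
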
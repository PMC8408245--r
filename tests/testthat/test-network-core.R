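test_that("reaction sides parse to compositions and back", {
  expect_equal(parse_side("2 A + 1 E"), c(A = 2, E = 1))
  expect_equal(parse_side("A + B"), c(A = 1, B = 1))
  expect_length(parse_side(""), 0)
  expect_equal(parse_side("A + A"), c(A = 2))
  expect_error(parse_side("-1 A"), "positive")
})

test_that("complex assembly deduplicates, indexes in first appearance order, and rejects loops", {
  m <- build_complexes(tibble::tibble(
    id = c("v1", "v2"), substrates = c("A + B", "C"), products = c("C", "A + B"),
    lb = 0, ub = 10))
  expect_equal(nrow(m$complexes), 2)
  expect_equal(m$complexes$label, c("A + B", "C"))
  A <- as.matrix(incidence_matrix(m))
  expect_equal(unname(A[, 1]), c(-1, 1))
  expect_equal(unname(A[, 2]), c(1, -1))

  # exchange reaction: the empty complex is a first-class node
  ex <- build_complexes(tibble::tibble(id = "e1", substrates = "", products = "A",
                                       lb = 0, ub = 10))
  expect_equal(nrow(ex$complexes), 2)
  expect_true("0" %in% ex$complexes$label)
  Y <- as.matrix(composition_matrix(ex))
  expect_equal(unname(Y[, match("0", ex$complexes$label)]), 0)

  expect_error(build_complexes(tibble::tibble(
    id = "loop", substrates = "A", products = "A", lb = 0, ub = 1)), "loop")
})

test_that("N = YA holds and matches direct per-reaction assembly on random networks", {
  single <- build_complexes(tibble::tibble(id = "r", substrates = "A", products = "B",
                                           lb = 0, ub = 1))
  expect_equal(unname(as.matrix(stoichiometric_matrix(single))[, 1]), c(-1, 1))

  toy <- toy_network()
  expect_equal(dim(stoichiometric_matrix(toy)), c(6L, 10L))

  for (s in 1:5) {
    g <- random_mass_action_network(small_spec(s))
    validate_network_model(g$model)  # includes entry-wise N = YA
    A <- incidence_matrix(g$model)
    expect_true(all(Matrix::colSums(A) == 0))
    expect_true(all(composition_matrix(g$model) >= 0))
  }
})

test_that("models round-trip through the reaction table up to complex deduplication", {
  for (s in 1:3) {
    g <- random_mass_action_network(small_spec(s))
    back <- build_complexes(reaction_table(g$model))
    expect_equal(reaction_table(back), reaction_table(g$model))
    expect_equal(back$complexes$key, g$model$complexes$key)
  }
})

test_that("reversible splitting counts, bounds and provenance follow the convention", {
  rxn <- tibble::tibble(
    id = c("a", "b", "c"),
    substrates = c("A", "B", "C"), products = c("B", "C", "A"),
    lb = c(0, -5, 0), ub = c(8, 5, 3),
    reversible = c(FALSE, TRUE, FALSE))
  m <- build_complexes(rxn)

  none <- split_reversible(build_complexes(rxn[rxn$reversible == FALSE, ]))
  expect_equal(nrow(none$reactions), 2)

  kept <- split_reversible(m, "keep")
  expect_equal(nrow(kept$reactions), 3 + 1)  # n + r
  expect_true(all(kept$reactions$lb == 0))
  expect_true(all(kept$reactions$ub == 8))  # maximum upper bound of the model
  expect_setequal(kept$reactions$id, c("a", "b__fwd", "b__bwd", "c"))
  ifwd <- match("b__fwd", kept$reactions$id)
  ibwd <- match("b__bwd", kept$reactions$id)
  Ak <- as.matrix(incidence_matrix(kept))
  expect_equal(Ak[, ifwd], -Ak[, ibwd])
  expect_equal(kept$reactions$provenance[[ifwd]], "b:fwd")

  all_rev <- split_reversible(m, "all-reversible")
  expect_equal(nrow(all_rev$reactions), 6)  # 2n

  bad <- rxn; bad$lb[2] <- 1
  expect_error(split_reversible(build_complexes(bad)), "contradicts")
})
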
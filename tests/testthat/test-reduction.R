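test_that("rate-constant rescaling matches the hand-computed cases", {
  expect_equal(rescale_rate_constant(2, c(1, 3), 1), 0.5)
  expect_equal(rescale_rate_constant(2, c(1, 3), 2), 1.5)
  expect_equal(rescale_rate_constant(5, c(7), 1), 5)  # m = 1 cancels
  expect_error(rescale_rate_constant(-1, c(1), 1), "positive")
})

test_that("removing a chain intermediate lumps the two reactions and keeps the flux id", {
  m <- build_complexes(tibble::tibble(
    id = c("ab", "bc"), substrates = c("A", "B"), products = c("B", "C"),
    lb = 0, ub = c(4, 9)))
  j <- match("B", m$complexes$label)
  step <- remove_single_outgoing(m, j)
  expect_equal(nrow(step$model$reactions), 1)
  expect_equal(step$model$reactions$id, "ab")  # inherits the incoming id/flux
  expect_equal(step$model$complexes$label[step$model$reactions$substrate], "A")
  expect_equal(step$model$complexes$label[step$model$reactions$product], "C")
  expect_equal(step$model$reactions$ub, 4)  # l = 1: capped by both bounds
  expect_equal(step$substitution$removed, "bc")
  expect_equal(step$substitution$expression$symbol, "ab")
  expect_false("B" %in% step$model$species$id)
})

test_that("removal counts follow l+1 deleted / l inserted and l+m deleted / ml inserted", {
  # two incoming, one outgoing
  m21 <- build_complexes(tibble::tibble(
    id = c("i1", "i2", "o1", "s1", "s2", "t1"),
    substrates = c("A", "B", "M", "", "", "C"),
    products = c("M", "M", "C", "A", "B", ""),
    lb = 0, ub = 10))
  j <- match("M", m21$complexes$label)
  red <- remove_single_outgoing(m21, j)$model
  expect_equal(nrow(red$reactions), 6 - 3 + 2)

  # two incoming, three outgoing under mass action: 5 deleted, 6 inserted
  m23 <- build_complexes(tibble::tibble(
    id = c("i1", "i2", "o1", "o2", "o3", "s1", "s2", "t1", "t2", "t3"),
    substrates = c("A", "B", "M", "M", "M", "", "", "C", "D", "E"),
    products = c("M", "M", "C", "D", "E", "A", "B", "", "", ""),
    lb = 0, ub = 10))
  kin <- stats::setNames(seq_len(10), m23$reactions$id)
  j <- match("M", m23$complexes$label)
  step <- remove_mass_action(m23, kin, j)
  expect_equal(nrow(step$model$reactions), 10 - 5 + 6)
  # rescaled constant of the (i1, o2) insertion: k_i1 * k_o2 / sum(k_out)
  expect_equal(step$kinetics[["i1__o2"]], 1 * 4 / (3 + 4 + 5))
  expect_equal(step$substitution$expression$coef, c(1, 2) / 12)
})

test_that("the worked example reduces as published under both kinetics", {
  toy <- toy_network()
  arb <- reduce_network(toy, mode = "arbitrary")
  expect_setequal(arb$removed_complexes, c("2 A", "A + E", "F"))
  expect_true("D" %in% arb$model$complexes$label)  # multi-outgoing: kept
  expect_equal(nrow(arb$model$complexes), 5)
  expect_setequal(arb$removed_species, c("A", "E", "F"))
  # the F removal's insertion is a discarded loop: no 2B -> 2B edge
  expect_true(all(arb$model$reactions$substrate != arb$model$reactions$product))

  ma <- reduce_network(toy, kinetics = toy_kinetics(), mode = "mass_action")
  expect_setequal(ma$removed_complexes, c("2 A", "A + E", "F", "D"))
  expect_equal(nrow(ma$model$complexes), 4)
  expect_setequal(ma$model$species$id, c("B", "C"))

  # symbolic mode removes the same complexes without numeric constants
  sym <- reduce_network(toy, kinetics = NULL, mode = "mass_action")
  expect_setequal(sym$removed_complexes, c("2 A", "A + E", "F", "D"))
  expect_true(is.character(sym$kinetics))
  expect_true(any(grepl("k\\(v", sym$kinetics)))
})

test_that("single-outgoing removals are order independent up to relabeling", {
  toy <- toy_network()
  labels <- c("F", "A + E", "2 A")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sigs <- vapply(perms, function(p) {
    m <- toy
    for (lbl in labels[p]) {
      m <- remove_single_outgoing(m, match(lbl, m$complexes$label))$model
    }
    edge_signature(m)
  }, "")
  expect_length(unique(sigs), 1)
  expect_equal(sigs[[1]], edge_signature(reduce_network(toy, mode = "arbitrary")$model))
})

test_that("reduction terminates at a fixpoint and never adds species", {
  nb <- no_balanced_model()
  res <- reduce_network(nb, mode = "arbitrary")
  expect_equal(nrow(res$rounds), 0)
  expect_length(res$substitutions, 0)
  expect_equal(reaction_table(res$model), reaction_table(nb))

  for (s in c(4, 13)) {
    g <- random_mass_action_network(small_spec(s))
    for (mode in c("arbitrary", "mass_action")) {
      r <- reduce_network(g$model, kinetics = g$kinetics, mode = mode)
      expect_lte(nrow(r$model$species), nrow(g$model$species))
    }
  }
})

test_that("parallel duplicates merge by summing constants under mass action", {
  # A -> M -> B alongside a pre-existing A -> B: the insertion merges into it
  m <- build_complexes(tibble::tibble(
    id = c("am", "mb", "ab", "sa", "tb"),
    substrates = c("A", "M", "A", "", "B"),
    products = c("M", "B", "B", "A", ""),
    lb = 0, ub = 10))
  kin <- c(am = 2, mb = 3, ab = 5, sa = 1, tb = 1)
  j <- match("M", m$complexes$label)
  step <- remove_mass_action(m, kin, j)
  expect_equal(sum(step$model$reactions$id == "ab"), 1)
  expect_equal(nrow(step$model$reactions), 3)
  expect_equal(step$kinetics[["ab"]], 5 + 2)  # k_ab + k_am * k_mb / k_mb
})

test_that("protected species block the removal of their complexes", {
  gm <- prepare_model(growth_network())
  res <- reduce_network(gm$model, mode = "arbitrary",
                        protect = biomass_species(gm$model))
  expect_equal(res$removed_complexes, "Q")
  none <- reduce_network(gm$model, mode = "arbitrary",
                         protect = c(biomass_species(gm$model), "Q"))
  expect_length(none$removed_complexes, 0)
})

test_that("tidy and glance summarize a reduction faithfully", {
  toy <- toy_network()
  res <- reduce_network(toy, kinetics = toy_kinetics(), mode = "mass_action")
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  expect_setequal(td$kind, "monomial")
  g <- glance(res)
  expect_equal(g$species_original, 6)
  expect_equal(g$species_reduced, 2)
  expect_equal(g$complexes_removed, 4)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
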
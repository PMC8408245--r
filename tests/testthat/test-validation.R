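test_that("conservation laws of the original hold in every reduced model", {
  toy <- toy_network()
  for (res in list(reduce_network(toy, mode = "arbitrary"),
                   reduce_network(toy, kinetics = toy_kinetics(), mode = "mass_action"))) {
    chk <- check_conservation_inclusion(res$original, res$model)
    expect_true(chk$ok)
    expect_lt(chk$max_residual, 1e-8)
  }

  # zero removals: identical matrices, trivially included
  nb <- no_balanced_model()
  res0 <- reduce_network(nb, mode = "arbitrary")
  expect_true(check_conservation_inclusion(res0$original, res0$model)$ok)

  for (s in c(5, 14)) {
    g <- random_mass_action_network(small_spec(s))
    r <- reduce_network(g$model, kinetics = g$kinetics, mode = "mass_action")
    expect_true(check_conservation_inclusion(r$original, r$model)$ok)
  }
})

test_that("sampled steady states map through the substitutions with tiny residuals", {
  toy <- toy_network()
  res <- reduce_network(toy, mode = "arbitrary")

  # the zero flux maps to zero
  v0 <- stats::setNames(rep(0, 10), toy$reactions$id)
  expect_equal(unname(apply_flux_map(res, v0)), rep(0, nrow(res$model$reactions)))

  ss <- check_steady_state_preserved(res, n_samples = 50, seed = 11)
  expect_true(ss$ok)
  expect_lt(ss$max_residual, 1e-9)
})

test_that("biomass-protected reduction leaves the growth optimum untouched", {
  gm <- prepare_model(growth_network())
  res <- reduce_network(gm$model, mode = "arbitrary",
                        protect = biomass_species(gm$model))
  o1 <- fba_optimum(res$original, flux_space(res$original))$value
  o2 <- fba_optimum(res$model, flux_space(res$model))$value
  expect_lt(abs(o1 - o2), 1e-6 * max(1, abs(o1)))

  # a biomass-optimal vertex survives the flux map with its biomass flux intact
  fs <- flux_space(res$original)
  v <- fba_optimum(res$original, fs)$solution
  vbar <- apply_flux_map(res, v)
  expect_equal(vbar[["bio"]], o1)
  expect_lt(max(abs(as.numeric(stoichiometric_matrix(res$model) %*% vbar))), 1e-9)
})

test_that("flux variability comparison classifies identical models as unchanged", {
  gm <- prepare_model(growth_network())$model
  same <- compare_fva(gm, gm)
  expect_true(all(same$classification == "same_range"))

  res <- reduce_network(gm, mode = "arbitrary",
                        protect = biomass_species(gm))
  cmp <- compare_fva(gm, res$model)
  expect_true(all(cmp$id %in% intersect(gm$reactions$id, res$model$reactions$id)))
  expect_true(all(cmp$classification %in% c("same_range", "wider", "narrower", "mixed")))
})

test_that("essential reactions stay essential in the reduced model", {
  gm <- prepare_model(growth_network())$model
  res <- reduce_network(gm, mode = "arbitrary",
                        protect = biomass_species(gm))
  ess <- compare_essentiality(gm, res$model)
  shared <- ess[ess$shared, ]
  expect_true(all(!shared$essential_original | shared$essential_reduced))
  expect_true(shared$essential_original[shared$id == "upt"])
  expect_true(shared$essential_reduced[shared$id == "upt"])
  expect_false(shared$essential_original[shared$id == "c1"])  # parallel route
})

test_that("a lumped replacement of an essential chain is itself essential", {
  # 0 -> A -> B -> 0 with objective on the outlet: removing B lumps the two
  # chain reactions into one, which must remain essential
  m <- chain_model(2)
  m$objective <- "r3"
  prep <- prepare_model(m)
  res <- reduce_network(prep$model, mode = "arbitrary",
                        protect = biomass_species(prep$model))
  expect_true(length(res$removed_complexes) >= 1)
  ess <- compare_essentiality(prep$model, res$model)
  shared <- ess[ess$shared & ess$id != "r3", ]
  expect_true(all(shared$essential_reduced))
})

test_that("jaccard similarity handles the documented cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 1)
})

test_that("compartment statistics mirror the global reduction", {
  toy <- toy_network()
  res <- reduce_network(toy, mode = "arbitrary")
  one <- compartment_reduction_stats(toy, res$model)
  expect_equal(nrow(one), 1)
  expect_equal(one$compartment, "unassigned")
  expect_equal(one$percent_removed, 100 * 3 / 6)

  # labelled variant: the removed species sit in their own compartment
  toy2 <- toy
  toy2$species$compartment <- ifelse(toy2$species$id %in% c("A", "E", "F"), "e", "c")
  res2 <- reduce_network(toy2, mode = "arbitrary")
  st <- compartment_reduction_stats(toy2, res2$model)
  expect_equal(st$percent_removed[st$compartment == "e"], 100)
  expect_equal(st$percent_removed[st$compartment == "c"], 0)

  none <- compartment_reduction_stats(toy, toy)
  expect_true(all(none$percent_removed == 0))
})

test_that("mass-action steady states satisfy the reduced equations", {
  toy <- toy_network()
  res <- reduce_network(toy, kinetics = toy_kinetics(), mode = "mass_action")
  x_star <- stats::setNames(rep(1, 6), toy$species$id)  # steady by construction
  chk <- check_concentration_preserved(res, toy_kinetics(), x_star)
  expect_lt(chk$residual_original, 1e-12)
  expect_true(chk$ok)
  expect_lt(chk$residual_reduced, 1e-8)
})
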
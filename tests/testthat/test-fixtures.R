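test_that("the worked-example transcription satisfies every stated constraint", {
  toy <- toy_network()
  expect_equal(nrow(toy$species), 6)
  expect_setequal(toy$species$id, c("A", "B", "C", "D", "E", "F"))
  expect_equal(nrow(toy$complexes), 8)
  expect_equal(nrow(toy$reactions), 10)
  expect_equal(toy$reactions$id, paste0("v", 1:10))

  # neighbourhoods of 2B
  j2b <- match("2 B", toy$complexes$label)
  in_nb <- toy$complexes$label[toy$reactions$substrate[toy$reactions$product == j2b]]
  out_nb <- toy$complexes$label[toy$reactions$product[toy$reactions$substrate == j2b]]
  expect_setequal(in_nb, c("D", "F"))
  expect_setequal(out_nb, c("A + E", "F"))

  # C is a sink
  jc <- match("C", toy$complexes$label)
  expect_length(which(toy$reactions$substrate == jc), 0)
  expect_gt(length(which(toy$reactions$product == jc)), 0)

  # balanced complexes 2A, A+E, F have one outgoing reaction; D has more
  rep <- identify_balanced(toy)
  expect_setequal(rep$label[rep$balanced], c("2 A", "A + E", "F", "D"))
  expect_equal(rep$n_out[rep$label %in% c("2 A", "A + E", "F")], rep(1L, 3))
  expect_gt(rep$n_out[rep$label == "D"], 1)

  expect_length(find_blocked_reactions(toy), 0)

  # the attached constants make the all-ones state a steady state
  rates <- mass_action_rates(toy, attr(toy, "kinetics"),
                             stats::setNames(rep(1, 6), toy$species$id))
  expect_lt(max(abs(rates$dx)), 1e-12)
})

test_that("planted networks are reproducible and honour their ground truth", {
  a <- random_mass_action_network(small_spec(6))
  b <- random_mass_action_network(small_spec(6))
  expect_equal(reaction_table(a$model), reaction_table(b$model))
  expect_equal(a$kinetics, b$kinetics)

  for (s in c(6, 23)) {
    g <- random_mass_action_network(small_spec(s))
    validate_network_model(g$model)
    rep <- identify_balanced(g$model, verify_trivial = TRUE)
    expect_true(all(g$planted %in% rep$complex[rep$balanced]))
    expect_true(all(rep$trivially_balanced[g$planted]))
    # the flux cone supports a nonzero steady state
    tot <- solve_lp(flux_space(g$model), rep(1, nrow(g$model$reactions)),
                    maximize = TRUE)
    expect_gt(tot$value, 1)
  }

  expect_error(planted_network_spec(n_reactions = 7), "even")
  expect_error(planted_network_spec(n_complexes = 8, n_reactions = 10), "too small")
})

test_that("vertex enumeration certifies forced-zero net fluxes on small models", {
  m <- chain_model(1)  # 0 -> S1 -> 0
  bal <- brute_force_balanced(m)
  expect_true(match("S1", m$complexes$label) %in% bal)

  toy <- toy_network()
  expect_setequal(toy$complexes$label[brute_force_balanced(toy)],
                  c("2 A", "A + E", "F", "D"))

  big <- random_mass_action_network(
    planted_network_spec(n_species = 9, n_complexes = 9, n_reactions = 16, seed = 1))
  expect_error(brute_force_balanced(big$model), "too large")
})

test_that("mass-action integration reaches steady states with conserved moieties", {
  # A <-> B with unit constants and total 2 relaxes to (1, 1)
  m <- build_complexes(tibble::tibble(
    id = c("f", "b"), substrates = c("A", "B"), products = c("B", "A"),
    lb = 0, ub = 10))
  x <- simulate_to_steady_state(m, c(f = 1, b = 1), c(A = 1.7, B = 0.3), tol = 1e-12)
  expect_equal(unname(x), c(1, 1), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(x), 2, tolerance = 1e-9)  # moiety total conserved

  # residual tracks the requested tolerance
  g <- random_mass_action_network(planted_network_spec(seed = 31))
  x0 <- stats::setNames(rep(1, nrow(g$model$species)), g$model$species$id)
  x_loose <- simulate_to_steady_state(g$model, g$kinetics, x0, tol = 1e-6)
  x_tight <- simulate_to_steady_state(g$model, g$kinetics, x0, tol = 1e-11)
  expect_lt(attr(x_tight, "residual"), attr(x_loose, "residual") + 1e-12)
  expect_lt(attr(x_tight, "residual"), 1e-11)

  # the ODE steady state of the original satisfies the reduced equations
  res <- reduce_network(g$model, kinetics = g$kinetics, mode = "mass_action")
  chk <- check_concentration_preserved(res, g$kinetics, x_tight)
  expect_true(chk$ok)
})
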
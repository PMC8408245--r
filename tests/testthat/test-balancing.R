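test_that("net flux bounds vanish where species balances force them to", {
  m <- chain_model(1)  # 0 -> S1 -> 0
  fs <- flux_space(m)
  j <- match("S1", m$complexes$label)
  expect_equal(net_flux_bounds(m, fs, j), c(0, 0))

  # whenever v = 0 is feasible, min <= 0 <= max for every complex
  toy <- toy_network()
  fst <- flux_space(toy)
  for (jj in seq_len(nrow(toy$complexes))) {
    if (length(in_r <- which(toy$reactions$product == jj)) == 0) next
    if (length(which(toy$reactions$substrate == jj)) == 0) next
    b <- net_flux_bounds(toy, fst, jj)
    expect_lte(b[1], 1e-12)
    expect_gte(b[2], -1e-12)
  }
})

test_that("the worked example's balanced and trivially balanced sets are exact", {
  toy <- toy_network()
  rep <- identify_balanced(toy, verify_trivial = TRUE)
  expect_setequal(rep$label[rep$balanced], c("2 A", "A + E", "F", "D"))
  expect_setequal(toy$complexes$label[classify_trivially_balanced(toy)],
                  c("D", "A + E", "F"))
  expect_false("2 A" %in% toy$complexes$label[classify_trivially_balanced(toy)])
  expect_true(rep$non_trivially_balanced[rep$label == "2 A"])
  # a non-balanced complex has an attainable nonzero net flux
  expect_gt(rep$net_max[rep$label == "2 B"], 1e-9)
  # sinks are never balanced
  expect_true(rep$sink[rep$label == "C"])
  expect_false(rep$balanced[rep$label == "C"])
})

test_that("chain ends act as sink and source and are excluded from balancing", {
  m <- build_complexes(tibble::tibble(
    id = c("r1", "r2"), substrates = c("S0", "M"), products = c("M", "P"),
    lb = 0, ub = 10))
  # S0 is a pure source and P a pure sink; the middle complex carries a
  # unique species but the ends do not qualify as trivially balanced
  expect_equal(m$complexes$label[classify_trivially_balanced(m)], "M")
  fs <- flux_space(m)
  rep <- identify_balanced(m, fs, screen = FALSE)
  expect_false(rep$balanced[rep$label == "S0"])
  expect_false(rep$balanced[rep$label == "P"])
})

test_that("LP identification agrees with vertex enumeration on random networks", {
  for (s in 1:20) {
    g <- random_mass_action_network(small_spec(s))
    fs <- flux_space(g$model)
    lp <- identify_balanced(g$model, fs, verify_trivial = TRUE)
    bf <- brute_force_balanced(g$model, fs)
    expect_equal(sort(lp$complex[lp$balanced]), sort(as.integer(bf)),
                 info = paste("seed", s))
  }
})

test_that("constraining the flux space never shrinks the balanced set", {
  toy <- toy_network()
  base <- identify_balanced(toy, flux_space(toy), verify_trivial = TRUE)
  # pin v9 near its maximum: a sub-polytope of the original space
  sub <- flux_space(toy, extra = tibble::tibble(
    coef = list(c(v9 = 1)), rel = ">=", rhs = 1))
  constrained <- identify_balanced(toy, sub, verify_trivial = TRUE)
  expect_true(all(constrained$balanced[base$balanced]))

  gm <- prepare_model(growth_network())
  b0 <- identify_balanced(gm$model, gm$fspace, verify_trivial = TRUE)
  fs1 <- biomass_floor(flux_space(gm$model), "bio", 1, optimum = gm$fba)
  b1 <- identify_balanced(gm$model, fs1, verify_trivial = TRUE)
  expect_true(all(b1$balanced[b0$balanced]))
})

test_that("trivially balanced complexes are balanced on blocked-free models", {
  for (s in c(2, 9, 17)) {
    g <- random_mass_action_network(small_spec(s))
    rep <- identify_balanced(g$model, verify_trivial = TRUE)
    expect_true(all(rep$balanced[rep$trivially_balanced]))
  }
})

test_that("flux coupling finds unit ratios along chains and rejects parallel branches", {
  m <- chain_model(2)  # 0 -> S1 -> S2 -> 0
  fs <- flux_space(m)
  fc <- fully_coupled(m, fs, "r1", "r2")
  expect_true(fc$coupled)
  expect_equal(fc$ratio, 1, tolerance = 1e-9)

  # two independent branches from one source complex are not coupled
  branch <- build_complexes(tibble::tibble(
    id = c("in", "b1", "b2", "o1", "o2"),
    substrates = c("", "A", "A", "B", "C"),
    products = c("A", "B", "C", "", ""),
    lb = 0, ub = 10))
  fb <- fully_coupled(branch, flux_space(branch), "b1", "b2")
  expect_false(fb$coupled)
})
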
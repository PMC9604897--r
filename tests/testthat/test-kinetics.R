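test_that("generalized mass action reduces to the expected closed forms", {
  ## S -> P, no modifiers: v = k [S]
  r <- reaction("re1", "S", "P")
  law <- assign_rate_law(r)
  expect_equal(eval_rate(law, c(S = 0.5, P = 0)), 0.5)

  ## adding one inhibitor at [I] = K_I exactly halves the rate
  r2 <- reaction("re2", "S", "P", modifiers = c(I = "inhibitor"))
  law2 <- assign_rate_law(r2)
  expect_equal(eval_rate(law2, c(S = 0.5, I = 1)), 0.25)

  ## catalysts multiply, activators saturate
  r3 <- reaction("re3", "S", "P",
                 modifiers = c(E = "catalyst", A = "activator"))
  law3 <- assign_rate_law(r3)
  expect_equal(eval_rate(law3, c(S = 1, E = 2, A = 1)), 2 * 1 / (1 + 1))

  ## source reaction: v = k times modifier factors
  r4 <- reaction("re4", products = "P", modifiers = c(E = "catalyst"))
  law4 <- assign_rate_law(r4)
  expect_equal(eval_rate(law4, c(P = 0, E = 3)), 3)

  ## stoichiometry enters as a power
  r5 <- reaction("re5", c(S = 2), "P")
  law5 <- assign_rate_law(r5)
  expect_equal(eval_rate(law5, c(S = 0.5, P = 0)), 0.25)
})

test_that("Michaelis-Menten form and its preconditions", {
  r <- reaction("re1", "S", "P", modifiers = c(E = "catalyst"))
  law <- assign_rate_law(r, form = "mm")
  ## V_max [E] [S] / (K_m + [S]) with defaults 1
  expect_equal(eval_rate(law, c(S = 1, E = 2)), 2 * 1 / (1 + 1))
  ## mm needs exactly one unit-stoichiometry substrate and a catalyst
  expect_error(assign_rate_law(reaction("r", c("A", "B"), "P",
                                        modifiers = c(E = "catalyst")),
                               form = "mm"), "one reactant")
  expect_error(assign_rate_law(reaction("r", "A", "P"), form = "mm"),
               "catalyst")
})

test_that("assign_all covers every reaction and honours policy/overrides", {
  m <- tiny_model()
  laws <- assign_all(m)
  expect_named(laws, c("re1", "re2"))
  expect_true(all(vapply(laws, function(l) l$form, "") == "gma"))

  laws_mm <- assign_all(m, policy = "mm_enzymes")
  expect_equal(laws_mm$re1$form, "gma")  # no catalyst
  expect_equal(laws_mm$re2$form, "mm")   # single substrate + catalyst

  laws_o <- assign_all(m, overrides = c(k_re1 = 2))
  expect_equal(eval_rate(laws_o$re1, c(a = 1, b = 0)), 2)
  expect_error(assign_all(m, overrides = c(nope = 1)), "unknown parameter")

  expect_length(assign_all(fruit_model("e")), 0)
})

test_that("rate laws are non-negative, monotone and have the right limits", {
  set.seed(42)
  r <- reaction("rx", c(S1 = 1, S2 = 2), "P",
                modifiers = c(E = "catalyst", A = "activator",
                              I = "inhibitor"))
  law <- assign_rate_law(r)
  species_names <- c("S1", "S2", "E", "A", "I")
  for (rep in seq_len(1000)) {
    st <- stats::setNames(stats::runif(5, 0, 5), species_names)
    v <- eval_rate(law, st)
    expect_true(is.finite(v) && v >= 0)
  }
  ## monotonicity by finite differences on random states
  for (rep in seq_len(50)) {
    st <- stats::setNames(stats::runif(5, 0.1, 3), species_names)
    v0 <- eval_rate(law, st)
    for (up in c("S1", "S2", "E", "A")) {
      st2 <- st; st2[[up]] <- st2[[up]] + 0.1
      expect_gte(eval_rate(law, st2), v0 - 1e-12)
    }
    st3 <- st; st3[["I"]] <- st3[["I"]] + 0.1
    expect_lte(eval_rate(law, st3), v0 + 1e-12)
  }
  ## limits: activator factor -> 1 as [A] -> Inf; inhibitor -> 1 as
  ## [I] -> 0; no-modifier gma is pure mass action
  st <- c(S1 = 1, S2 = 1, E = 1, A = 1e9, I = 0)
  expect_equal(eval_rate(law, st), 1, tolerance = 1e-6)
  plain <- assign_rate_law(reaction("rp", c(S1 = 1, S2 = 2), "P"))
  expect_equal(eval_rate(plain, c(S1 = 2, S2 = 3)), 2 * 9)
})

test_that("text and MathML renderings are faithful", {
  r <- reaction("re1", "S", "P")
  law <- assign_rate_law(r)
  expect_equal(render_expression(law, "text"), "k_re1 * S")

  r6 <- reaction("re6", "mycelium_aggregation", "pinhead_formation",
                 modifiers = c(hydrophobin = "catalyst",
                               pofst_protein = "inhibitor"))
  law6 <- assign_rate_law(r6)
  txt <- render_expression(law6, "text")
  expect_match(txt, "k_re6 \\* mycelium_aggregation \\* hydrophobin")
  expect_match(txt, "K_I_re6_pofst_protein / \\(K_I_re6_pofst_protein \\+ pofst_protein\\)")

  ## MathML re-parses to a numerically identical evaluator
  r7 <- reaction("re7", c(S = 2), "P",
                 modifiers = c(E = "catalyst", A = "activator",
                               I = "inhibitor"))
  law7 <- assign_rate_law(r7)
  f <- mathml_evaluator(render_expression(law7, "mathml"))
  set.seed(7)
  for (rep in seq_len(10)) {
    st <- stats::setNames(stats::runif(4, 0, 3), c("S", "E", "A", "I"))
    vals <- c(st, law7$parameters)
    expect_equal(f(vals), eval_rate(law7, st), tolerance = 1e-12)
  }
})
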
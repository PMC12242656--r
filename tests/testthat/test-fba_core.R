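# FBA / pFBA / FVA against hand-derived and external oracles

test_that("toy FBA optima match the closed-form balance algebra", {
  toy <- make_toy_model()
  # O2-limited regime (glc 10, O2 15)
  s <- solve_fba(toy, bounds = list(EX_glc__D_e = c(-10, 0)))
  expect_equal(s$objective_value, toy_mu_max(10, 15), tolerance = 1e-9)
  # O2 slack regime
  s2 <- solve_fba(toy, bounds = list(EX_glc__D_e = c(-10, 0),
                                     EX_o2_e = c(-1000, 0)))
  expect_equal(s2$objective_value, toy_mu_max(10, 1000), tolerance = 1e-9)
  expect_equal(s2$objective_value, 10 / 13, tolerance = 1e-9)
  # intermediate uptakes, both regimes
  for (g in c(2, 5, 7.8, 9)) {
    sg <- solve_fba(toy, bounds = list(EX_glc__D_e = c(-g, 0)))
    expect_equal(sg$objective_value, toy_mu_max(g, 15), tolerance = 1e-8,
                 info = paste("g =", g))
  }
})

test_that("optimal solutions satisfy mass balance and bounds", {
  toy <- toy_phb()
  s <- solve_fba(toy, bounds = list(EX_glc__D_e = c(-10, 0)))
  S <- stoichiometric_matrix(toy)
  expect_lt(max(abs(S %*% s$fluxes)), 1e-6)
  bd <- model_bounds(toy)
  expect_true(all(s$fluxes >= bd$lb - 1e-9))
  expect_true(all(s$fluxes <= bd$ub + 1e-9))
})

test_that("closing every bound gives the zero solution", {
  toy <- make_toy_model()
  ov <- lapply(names(toy$reactions), function(i) c(0, 0))
  names(ov) <- names(toy$reactions)
  s <- solve_fba(toy, bounds = ov)
  expect_equal(s$objective_value, 0)
  expect_true(all(abs(s$fluxes) <= 1e-12))
})

test_that("the objective is invariant to reaction column ordering", {
  toy <- make_toy_model()
  perm <- rev(seq_along(toy$reactions))
  shuffled <- metabolic_model(toy$metabolites, toy$reactions[perm],
                              id = "shuffled",
                              biomass_reaction_id = "BIOMASS_toy")
  a <- solve_fba(toy, bounds = list(EX_glc__D_e = c(-10, 0)))
  b <- solve_fba(shuffled, bounds = list(EX_glc__D_e = c(-10, 0)))
  expect_equal(a$objective_value, b$objective_value, tolerance = 1e-9)
})

test_that("overrides must reference existing reactions", {
  expect_error(solve_fba(make_toy_model(), bounds = list(NOPE = c(0, 0))),
               "NOPE")
  expect_error(solve_fba(make_toy_model(), objective = "NOPE"), "NOPE")
})

test_that("FBA objectives agree with an independent solver under random bounds", {
  skip_if_not(scipy_available(), "python/scipy not on PATH")
  toy <- toy_phb()
  S <- stoichiometric_matrix(toy)
  bd <- model_bounds(toy)
  set.seed(7)
  for (case in 1:5) {
    lb <- bd$lb
    lb["EX_glc__D_e"] <- -stats::runif(1, 1, 12)
    lb["EX_o2_e"] <- -stats::runif(1, 2, 20)
    mine <- dyseep:::lp_solve(bd$obj, S, rep(0, nrow(S)), lb, bd$ub)
    ref <- scipy_lp(unname(bd$obj), unname(S), unname(lb), unname(bd$ub))
    expect_equal(mine$value, ref$value, tolerance = 1e-7)
  }
})

test_that("FVA of a uniquely-determined optimum is fully degenerate", {
  toy <- make_toy_model()
  fva <- run_fva(toy, bounds = list(EX_glc__D_e = c(-10, 0)))
  expect_true(all(fva$min <= fva$max))
  expect_lt(max(fva$max - fva$min), 1e-6)
  # the (parsimonious) FBA flux lies inside every range
  s <- solve_fba(toy, bounds = list(EX_glc__D_e = c(-10, 0)))
  expect_true(all(s$fluxes[fva$reaction] >= fva$min - 1e-6))
  expect_true(all(s$fluxes[fva$reaction] <= fva$max + 1e-6))
})

test_that("a parallel pathway produces the oracle's non-degenerate range", {
  toy <- make_toy_model()
  # duplicate the transport step: the pair shares a total flux of 10, so
  # each branch ranges over [0, 10] at the fixed optimum
  toy <- dyseep:::.add_reactions(toy, list(
    reaction("GLCt_dup", c(glc__D_e = -1, glc__D_c = 1), 0, 1000)))
  fva <- run_fva(toy, bounds = list(EX_glc__D_e = c(-10, 0)),
                 reactions = c("GLCt", "GLCt_dup", "BIOMASS_toy"))
  for (id in c("GLCt", "GLCt_dup")) {
    row <- fva[fva$reaction == id, ]
    expect_equal(row$min, 0, tolerance = 1e-8)
    expect_equal(row$max, 10, tolerance = 1e-8)
  }
  bm <- fva[fva$reaction == "BIOMASS_toy", ]
  expect_equal(bm$max - bm$min, 0, tolerance = 1e-8)
})

test_that("blocked reactions report the [0, 0] range", {
  toy <- make_toy_model()
  fva <- run_fva(toy, bounds = list(EX_glc__D_e = c(-10, 0),
                                    LDHFERM = c(0, 0)),
                 reactions = "LDHFERM")
  expect_equal(unname(unlist(fva[1, c("min", "max")])), c(0, 0))
})

test_that("pinning any reaction inside its FVA range stays feasible at the optimum", {
  toy <- toy_phb()
  ov <- list(EX_glc__D_e = c(-10, 0))
  fva <- run_fva(toy, bounds = ov)
  opt <- attr(fva, "objective_value")
  set.seed(1)
  picks <- sample(nrow(fva), 6)
  for (i in picks) {
    pin <- stats::runif(1, fva$min[i], fva$max[i])
    s <- solve_fba(toy, bounds = c(ov, stats::setNames(
      list(c(pin, pin)), fva$reaction[i])), parsimonious = FALSE)
    expect_equal(s$status, "optimal", info = fva$reaction[i])
    expect_equal(s$objective_value, opt, tolerance = 1e-6,
                 info = fva$reaction[i])
  }
})

test_that("fraction_of_optimum relaxes the envelope", {
  toy <- make_toy_model()
  ov <- list(EX_glc__D_e = c(-10, 0))
  tight <- run_fva(toy, bounds = ov, reactions = "EX_ac_e")
  loose <- run_fva(toy, bounds = ov, reactions = "EX_ac_e",
                   fraction_of_optimum = 0.5)
  expect_gte(loose$max[1] - loose$min[1] + 1e-9,
             tight$max[1] - tight$min[1])
  expect_gt(loose$max[1] - loose$min[1], 1)
})

test_that("infeasible problems yield a status, never an exception", {
  toy <- make_toy_model()
  s <- solve_fba(toy, bounds = list(BIOMASS_toy = c(5, 5),
                                    EX_glc__D_e = c(-1, 0)))
  expect_equal(s$status, "infeasible")
  expect_true(is.na(s$objective_value))
  expect_error(run_fva(toy, bounds = list(BIOMASS_toy = c(5, 5),
                                          EX_glc__D_e = c(-1, 0))),
               "status")
})
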
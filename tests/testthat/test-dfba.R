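# dynamic FBA: closed-form checks, invariants, events

test_that("a pure growth batch matches the closed-form solution", {
  # with oxygen non-limiting the toy biomass yield is exactly 1/13 g/mmol,
  # so X_final = X0 + C0/13 independent of the time course
  toy <- make_toy_model()
  kin <- uptake_kinetics(vmax = 10.5, K = 0.015, Ki = 8941.7, vo2max = 1000)
  setup <- test_setup()
  res <- simulate_batch(toy, kin, setup)
  C0 <- 25 / 180.16 * 1000
  expect_equal(res$final_biomass, toy_batch_final_biomass(0.25, C0),
               tolerance = 1e-3)
  expect_equal(res$terminal, "glucose_depleted")
  expect_lt(res$glucose_residual, setup$glucose_threshold * 1.01)
  # halving the integrator tolerances moves the result by < 0.1 % relative
  tight <- test_setup(rtol = setup$rtol / 2, atol = setup$atol / 2)
  res2 <- simulate_batch(toy, kin, tight)
  expect_equal(res2$final_biomass, res$final_biomass, tolerance = 1e-3)
})

test_that("zero inoculum means nothing happens", {
  toy <- make_toy_model()
  kin <- default_parameters("ecoli", "aerobic")
  res <- simulate_batch(toy, kin, test_setup(initial_biomass = 0, t_max = 5))
  expect_equal(res$final_biomass, 0)
  expect_equal(res$glucose_consumed, 0)
  tr <- res$trajectory
  expect_equal(max(abs(tr$glucose - tr$glucose[1])), 0)
})

test_that("trajectories are monotone and mass-consistent", {
  toy <- toy_phb()
  kin <- default_parameters("ecoli", "aerobic")
  setup <- test_setup()
  res <- simulate_batch(toy, kin, setup, fixed_fluxes = c(EX_phb_e = 5))
  tr <- res$trajectory
  expect_true(all(diff(tr$X) >= -1e-9))          # mu >= 0 throughout
  expect_true(all(diff(tr$glucose) <= 1e-9))     # substrate only consumed
  # definitional identities of the derived quadruple
  expect_equal(res$productivity * res$t_op, res$titer, tolerance = 1e-9)
  expect_equal(res$yield * setup$initial_glucose, res$titer,
               tolerance = 1e-12)
  # PHB mass from the trajectory equals titer x volume
  phb_g_l <- tr$phb[nrow(tr)] * 86 / 1000
  expect_equal(phb_g_l * setup$working_volume,
               res$titer * setup$working_volume, tolerance = 1e-9)
  expect_true(res$phb_content >= 0 && res$phb_content <= 100)
})

test_that("carbon balances exactly across the toy batch", {
  toy <- toy_phb()
  kin <- default_parameters("ecoli", "aerobic")
  res <- simulate_batch(toy, kin, test_setup(),
                        fixed_fluxes = c(EX_phb_e = 4))
  tr <- res$trajectory
  last <- tr[nrow(tr), ]
  # carbon sinks (mmol C / L): biomass stores 4 C per gram (2 acetyl groups),
  # PHB 4 C per monomer, acetate 2, lactate 3, CO2 1
  stored <- 4 * (last$X - 0.25) + 4 * last$phb + 2 * last$acetate +
    3 * last$lactate + 1 * last$co2
  consumed_c <- 6 * (res$glucose_consumed / res$setup$working_volume)
  expect_equal(stored, consumed_c, tolerance = 1e-4 * consumed_c)
})

test_that("an unsustainable fixed flux ends in metabolic arrest, not an error", {
  toy <- toy_phb()
  kin <- default_parameters("ecoli", "aerobic")
  # 9.9 is feasible at 25 g/L but infeasible once uptake falls below it
  res <- simulate_batch(toy, kin, test_setup(),
                        fixed_fluxes = c(EX_phb_e = 9.9))
  expect_equal(res$terminal, "metabolic_arrest")
  expect_gt(res$glucose_residual, res$setup$glucose_threshold)
  # a flux that is infeasible from the very start errors before integration
  expect_error(simulate_batch(toy, kin, test_setup(),
                              fixed_fluxes = c(EX_phb_e = 20)),
               "infeasible")
})

test_that("two-phase switching honours the glucose allocation", {
  toy <- toy_phb()
  kin <- default_parameters("ecoli", "aerobic")
  setup <- test_setup()
  total <- 25 / 180.16 * 1000
  res <- simulate_two_phase(toy, kin, setup, growth_fraction = 0.5)
  sw <- res$events[res$events$event == "phase_switch", ]
  expect_equal(nrow(sw), 1L)
  # cumulative consumption at the switch equals half the allotment
  i <- which.min(abs(res$trajectory$time - sw$time))
  consumed <- total - res$trajectory$glucose[i]
  expect_equal(consumed, 0.5 * total, tolerance = 1e-3 * total)

  # fraction 0: no growth phase at all
  r0 <- simulate_two_phase(toy, kin, setup, growth_fraction = 0)
  expect_equal(r0$final_biomass, 0.25, tolerance = 1e-6)
  expect_gt(r0$titer, 10)

  # fraction 1 degenerates to the plain growth batch
  r1 <- simulate_two_phase(toy, kin, setup, growth_fraction = 1)
  rb <- simulate_batch(toy, kin, setup)
  expect_equal(r1$final_biomass, rb$final_biomass, tolerance = 1e-6)
  expect_equal(r1$titer, rb$titer, tolerance = 1e-9)
})

test_that("derived-quantity helpers implement the standard definitions", {
  expect_equal(phb_content(12.60, 2.15), 100 * 12.60 / (2.15 + 12.60))
  expect_equal(phb_content(0, 5), 0)
  expect_equal(phb_content(5, 0), 100)
  expect_equal(phb_content(0, 0), 0)
  expect_equal(phb_yield(9.17, 25), 9.17 / 25)
  expect_equal(phb_yield(3, 0), 0)
})
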
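# per-batch economics: each term against hand substitution, then assembly

# a minimal simulation_result stub with a constant-biomass trajectory
fake_result <- function(titer = 0, biomass = 0, t_op = 10, X_const = NULL,
                        regime = "aerobic", vo2max = 15,
                        oxygen_mol = 0, glucose_mol = 0,
                        volume = 200, initial_glucose = 25) {
  X <- if (is.null(X_const)) biomass else X_const
  structure(list(
    trajectory = data.frame(time = c(0, t_op), X = c(X, X)),
    final_biomass = biomass, titer = titer,
    yield = phb_yield(titer, initial_glucose), t_op = t_op,
    productivity = if (t_op > 0) titer / t_op else 0,
    phb_content = phb_content(titer, biomass),
    oxygen_consumed = oxygen_mol, glucose_consumed = glucose_mol,
    glucose_residual = 0, x_integral = X * t_op,
    events = data.frame(time = t_op, event = "glucose_depleted"),
    terminal = "glucose_depleted", regime = regime, vo2max = vo2max,
    setup = batch_setup(working_volume = volume,
                        initial_glucose = initial_glucose,
                        regime = regime)
  ), class = "simulation_result")
}

test_that("revenue is titer x volume x recovery x purity x price", {
  p <- econ_parameters()
  expect_equal(revenue(fake_result(titer = 0), p), 0)
  expect_equal(revenue(fake_result(titer = 12.60), p),
               12.60 * 200 * 0.97 * 0.98 * 5.5)
  p1 <- econ_parameters(recovery = 1, purity = 1)
  expect_equal(revenue(fake_result(titer = 12.60), p1), 12.60 * 200 * 5.5)
})

test_that("raw material charges the fixed glucose allotment", {
  p <- econ_parameters()
  expect_equal(raw_material_cost(fake_result(), p), 5000 * 350 / 1000)
  # identical across scenarios: independent of the outcome fields
  expect_equal(raw_material_cost(fake_result(titer = 14), p),
               raw_material_cost(fake_result(titer = 0), p))
})

test_that("aeration cost matches the closed form for constant biomass", {
  p <- econ_parameters()
  X <- 4; t <- 10
  res <- fake_result(X_const = X, t_op = t, vo2max = 15)
  # hand substitution: OUR = vo2max*X mmol/L/h over the whole reactor,
  # inflated by transfer efficiency, ideal-gas air flow, compressor power
  our_mmol_h <- 15 * X * 200 * 1000
  air_mol_h <- our_mmol_h / 0.20 / 1000 / 0.2095
  q <- air_mol_h * 8.314 * 298.15 / 101325 / 3600
  pc_kw <- 101325 * q / 0.7 * (1.4 / 0.4) * ((263200 / 101325)^(0.4 / 1.4) - 1) / 1000
  expect_equal(aeration_cost(res, p), pc_kw * t * 126 / 1000,
               tolerance = 1e-12)
  # X = 0 -> no demand; linear in the electricity price
  expect_equal(aeration_cost(fake_result(X_const = 0), p), 0)
  p2 <- econ_parameters(electricity_price = 252)
  expect_equal(aeration_cost(res, p2), 2 * aeration_cost(res, p))
  expect_message(aeration_cost(fake_result(regime = "anaerobic",
                                           vo2max = 0), p), "anaerobic")
})

test_that("the stirring correlation inverts consistently", {
  # P_S = V * (kLa / (0.002 * Vs^0.2))^(1/0.7) must re-substitute into
  # kLa = 0.002 (P_S/V)^0.7 Vs^0.2
  kla <- 0.05; V <- 200; vs <- 0.04
  ps <- V * (kla / (0.002 * vs^0.2))^(1 / 0.7)
  expect_equal(0.002 * (ps / V)^0.7 * vs^0.2, kla, tolerance = 1e-12)
  # power demand is monotone in the kLa requirement
  ps2 <- V * (2 * kla / (0.002 * vs^0.2))^(1 / 0.7)
  expect_gt(ps2, ps)
  # zero oxygen demand -> zero stirring cost
  p <- econ_parameters()
  expect_equal(as.numeric(agitation_cost_aerobic(
    fake_result(X_const = 0), p)), 0)
  # a demanding culture trips the kLa ceiling flag
  p3 <- econ_parameters(reactor = list(kla_ceiling_s = 1e-5))
  expect_warning(cost <- agitation_cost_aerobic(
    fake_result(X_const = 5), p3), "kLa")
  expect_true(attr(cost, "kla_exceeded"))
})

test_that("anaerobic agitation is the constant cubic power law", {
  p <- econ_parameters()
  res <- fake_result(regime = "anaerobic", vo2max = 0, t_op = 10)
  ps_w <- 4 * 1032 * 0.83^3 * 5^5
  expect_equal(agitation_cost_anaerobic(res, p),
               ps_w * 10 / 1000 * 126 / 1000, tolerance = 1e-12)
  expect_equal(agitation_cost_anaerobic(
    fake_result(regime = "anaerobic", t_op = 0), p), 0)
  # doubling the speed multiplies power by 8
  p8 <- econ_parameters(reactor = list(anaerobic_agitation = 2 * 0.83))
  expect_equal(agitation_cost_anaerobic(res, p8),
               8 * agitation_cost_anaerobic(res, p), tolerance = 1e-12)
})

test_that("cooling heat equals the proportionality constants by substitution", {
  p <- econ_parameters()
  expect_equal(cooling_cost(fake_result(oxygen_mol = 0), p), 0)
  # aerobic: 0.50 kJ per mmol O2 consumed
  res_a <- fake_result(oxygen_mol = 1000)
  expect_equal(cooling_cost(res_a, p),
               0.50 * 1000 * 1000 / 3600 / 4 * 126 / 1000,
               tolerance = 1e-12)
  # anaerobic: 235 kJ per mol glucose; 5000 kg consumed
  res_n <- fake_result(regime = "anaerobic",
                       glucose_mol = 5e6 / 180.16)
  expect_equal(cooling_cost(res_n, p),
               235 * (5e6 / 180.16) / 3600 / 4 * 126 / 1000,
               tolerance = 1e-12)
})

test_that("upstream is a scenario-independent constant with the stated steam demand", {
  p <- econ_parameters()
  us <- upstream_cost(p)
  # steam mass: medium mass x cp x deltaT / latent heat
  steam_kg <- (1032 * 200) * 4.18 * 96 / 2202
  expect_equal(attr(us, "breakdown")[["sterilization"]],
               steam_kg * 4 / 1000, tolerance = 1e-12)
  expect_equal(attr(us, "breakdown")[["medium"]],
               sum(p$medium$conc_g_l * 200 * p$medium$price_usd_kg),
               tolerance = 1e-12)
  # zero prices -> zero cost
  med0 <- p$medium; med0$price_usd_kg <- 0
  p0 <- econ_parameters(steam_price = 0, medium = med0)
  expect_equal(as.numeric(upstream_cost(p0)), 0)
})

test_that("downstream line items follow the coefficient table", {
  p <- econ_parameters()
  res <- fake_result(titer = 12.60, biomass = 2.15)
  it <- attr(downstream_cost(res, p), "items")
  total_kg <- (2.15 + 12.60) * 200
  residual_kg <- 2.15 * 200
  expect_equal(it[["homogenization"]], 0.35 * total_kg * 126 / 1000)
  expect_equal(it[["centrifugation"]], 0.5 * 200 * 3 * 126 / 1000)
  expect_equal(it[["extraction"]], 9.25 * residual_kg * 1.15)
  expect_equal(it[["drying"]], 2 * 12.60 * 200 * 4 / 1000)
  expect_equal(it[["wastewater"]], 200 * 0.5)
  # empty broth: only the volume-driven terms remain
  it0 <- attr(downstream_cost(fake_result(), p), "items")
  expect_equal(unname(it0[c("homogenization", "extraction", "drying")]),
               c(0, 0, 0))
  expect_gt(it0[["centrifugation"]], 0)
  expect_gt(it0[["wastewater"]], 0)
  # doubling titer doubles drying but leaves the volume/residual terms alone
  it2 <- attr(downstream_cost(fake_result(titer = 25.2, biomass = 2.15),
                              p), "items")
  expect_equal(it2[["drying"]], 2 * it[["drying"]])
  expect_equal(it2[["centrifugation"]], it[["centrifugation"]])
  expect_equal(it2[["wastewater"]], it[["wastewater"]])
  expect_equal(it2[["extraction"]], it[["extraction"]])
})

test_that("gross profit assembles exactly and batches are a real-valued rate", {
  p <- econ_parameters()
  res <- fake_result(titer = 12.60, biomass = 2.15, X_const = 2.15,
                     t_op = 15, oxygen_mol = 500, glucose_mol = 5e6 / 180.16)
  be <- monthly_gross_profit(res, p)
  expect_identical(be$gross_profit,
                   be$revenue - (be$raw_material + sum(be$operation) +
                                 be$upstream + sum(be$downstream)))
  expect_equal(be$monthly_gross_profit,
               be$gross_profit * be$n_batches_per_month)
  # turnaround arithmetic
  expect_equal(monthly_gross_profit(fake_result(t_op = 708),
                                    p)$n_batches_per_month, 1)
  expect_equal(monthly_gross_profit(fake_result(t_op = 12),
                                    p)$n_batches_per_month, 30)
})

test_that("with per-batch profit held fixed, MGP falls as batches lengthen", {
  # strip every time-dependent cost so GP is identical across operation
  # times, isolating the 720/(t+12) batch-rate factor
  med0 <- econ_parameters()$medium; med0$price_usd_kg <- 0
  p <- econ_parameters(glucose_price = 0, steam_price = 0,
                       electricity_price = 0, solvent_price = 0,
                       wastewater_price = 0, medium = med0)
  mgp <- vapply(c(5, 10, 20, 50), function(t) {
    monthly_gross_profit(fake_result(titer = 10, t_op = t), p)$monthly_gross_profit
  }, 0)
  expect_true(all(diff(mgp) < 0))
  gp <- vapply(c(5, 10, 20, 50), function(t) {
    monthly_gross_profit(fake_result(titer = 10, t_op = t), p)$gross_profit
  }, 0)
  expect_equal(max(gp) - min(gp), 0)
})
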
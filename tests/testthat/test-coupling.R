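# hand-made surrogates used across the coupling tests
twin_surrogate <- function(r_out = 1e-3, r_b = 1e-3) {
  outlets <- outlet_set(c("A", "B"), c(r_out, r_b))
  segs <- data.frame(from = c("CCA", "CCA"), to = c("A", "B"),
                     radius = c(r_out, r_b))
  domain_surrogate(list(name = "CCA", radius = 2e-3, velocity = 0.2),
                   segs, outlets)
}

three_outlet_surrogate <- function() {
  outlets <- outlet_set(c("ICA", "STA", "FA"),
                        c(2.7e-3, 1.0e-3, 0.8e-3),
                        is_ica = c(TRUE, FALSE, FALSE))
  segs <- data.frame(
    from = c("CCA", "CCA", "J1", "J1"),
    to = c("ICA", "J1", "STA", "FA"),
    radius = c(2.7e-3, 1.6e-3, 1.0e-3, 0.8e-3)
  )
  domain_surrogate(list(name = "CCA", radius = 3.2e-3, velocity = 0.25),
                   segs, outlets)
}

test_that("flow/velocity conversions are exact inverses with area scaling", {
  expect_identical(inlet_flow_from_velocity(3e-3, 0), 0)
  expect_equal(inlet_flow_from_velocity(3e-3, 0.3), 0.3 * pi * 9e-6,
               tolerance = 1e-14)
  # doubling the radius quadruples the flow
  expect_equal(inlet_flow_from_velocity(2e-3, 0.3) /
                 inlet_flow_from_velocity(1e-3, 0.3), 4, tolerance = 1e-14)
  # round trip
  q <- inlet_flow_from_velocity(1.3e-3, 0.47)
  expect_equal(velocity_from_flow(q, 1.3e-3), 0.47, tolerance = 1e-14)
  expect_identical(velocity_from_flow(0, 1e-3), 0)
  expect_equal(velocity_from_flow(2e-6, 1e-3), 2e-6 / (pi * 1e-6),
               tolerance = 1e-14)
  expect_error(inlet_flow_from_velocity(1e-3, -0.1), "non-negative")
})

test_that("boundary-condition attachment builds the right terminal model per variant", {
  outlets <- outlet_set("STA", 1e-3)
  zp <- attach_boundary_conditions(outlets, "zero_pressure")
  expect_identical(zp$bcs[[1]]$r_base, 0)
  expect_null(zp$bcs[[1]]$tree)

  pr <- attach_boundary_conditions(outlets, "present_0d")
  # matches the standalone resistance computation on the same outlet
  tr <- build_tree(1e-3)
  expect_equal(pr$bcs[[1]]$r_base, compute_profile(tr, 0)$root_resistance,
               tolerance = 1e-12)
  expect_gt(pr$bcs[[1]]$r_base, 0)

  cv <- attach_boundary_conditions(outlets, "conventional_0d")
  # same machinery, different lambda schedule and terminal closure
  expect_true(all(cv$bcs[[1]]$tree$levels$lambda == 30))
  expect_false(all(pr$bcs[[1]]$tree$levels$lambda == 30))
  expect_identical(cv$bcs[[1]]$p_terminal_pa, 0)
  expect_equal(pr$bcs[[1]]$p_terminal_pa, mmhg_to_pa(30))
  expect_equal(cv$bcs[[1]]$tree$levels$radius, pr$bcs[[1]]$tree$levels$radius)

  expect_error(attach_boundary_conditions(outlets, "windkessel"), "variant")
})

test_that("identical twin outlets receive exactly half the inlet flow each", {
  sg <- twin_surrogate()
  for (v in c("zero_pressure", "conventional_0d", "present_0d")) {
    s <- solve_coupled(sg, v)
    expect_equal(s$outlets$flow[1], s$outlets$flow[2], tolerance = 1e-12)
    expect_equal(s$outlets$flow[1], s$inlet_flow / 2, tolerance = 1e-12)
  }
})

test_that("enlarging an outlet strictly increases its flow share (zero pressure)", {
  s1 <- solve_coupled(twin_surrogate(), "zero_pressure")
  s2 <- solve_coupled(twin_surrogate(r_out = 1.3e-3), "zero_pressure")
  share1 <- s1$outlets$flow[1] / s1$inlet_flow
  share2 <- s2$outlets$flow[1] / s2$inlet_flow
  expect_gt(share2, share1)
})

test_that("iterative solver matches one-shot nodal analysis for fixed resistances", {
  sg <- three_outlet_surrogate()
  q_in <- inlet_flow_from_velocity(sg$inlet$radius, sg$inlet$velocity)
  # conventional variant: resistances are flow-independent
  s <- solve_coupled(sg, "conventional_0d")
  r_fixed <- setNames(s$outlets$lumped_resistance, s$outlets$name)
  nod <- solve_network_nodal(sg, r_fixed, q_in)
  expect_equal(s$outlets$flow, as.numeric(nod$outlet_flows[s$outlets$name]),
               tolerance = 1e-8)
  expect_equal(s$outlets$pressure_pa,
               as.numeric(nod$outlet_pressures[s$outlets$name]),
               tolerance = 1e-8)
  # mixed zero / non-zero lumped resistances
  r_mixed <- setNames(c(0, 5e10, 2e11), s$outlets$name)
  it <- solve_surrogate_tree(sg, r_mixed, q_in, 0.0046)
  nod2 <- solve_network_nodal(sg, r_mixed, q_in)
  expect_equal(as.numeric(it$outlet_flows),
               as.numeric(nod2$outlet_flows), tolerance = 1e-8)
})

test_that("mass is conserved to machine precision in every variant", {
  fx <- fixture_config(seed = 5, n_branches = 8)
  sg <- make_surrogate(make_outlet_set(fx), fx)
  for (v in c("zero_pressure", "conventional_0d", "present_0d")) {
    s <- solve_coupled(sg, v)
    expect_lt(abs(sum(s$outlets$flow) - s$inlet_flow) / s$inlet_flow, 1e-12)
  }
})

test_that("present-model coupling converges onto the terminal-pressure fixed point", {
  fx <- fixture_config(seed = 13, n_branches = 9)
  sg <- make_surrogate(make_outlet_set(fx), fx)
  s <- solve_coupled(sg, "present_0d")
  expect_true(s$converged)
  expect_lt(s$residual, 1e-4)
  # each outlet's lumped pressure decomposes as tree drop + terminal pressure
  bcs <- attach_boundary_conditions(sg$outlets, "present_0d")
  r_base <- vapply(bcs$bcs, function(b) b$r_base, numeric(1))
  p_term <- s$outlets$pressure_pa - s$outlets$flow * r_base
  expect_equal(pa_to_mmhg(p_term), rep(30, nrow(s$outlets)),
               tolerance = 1e-4)
  # outlet pressures lie strictly between terminal and inlet pressure
  expect_true(all(s$outlets$pressure_pa > mmhg_to_pa(30)))
  expect_true(all(s$outlets$pressure_pa < s$inlet_pressure))
})

test_that("outlet pressures order as structured >= conventional >= zero pressure", {
  fx <- fixture_config(seed = 21, n_branches = 7)
  sg <- make_surrogate(make_outlet_set(fx), fx)
  cmp <- compare_variants(sg)
  p <- function(v) cmp$table$pressure_mmhg[cmp$table$variant == v]
  expect_true(all(p("present_0d") >= p("conventional_0d")))
  expect_true(all(p("conventional_0d") >= 0))
  expect_true(all(p("zero_pressure") == 0))
})

test_that("comparison error statistics match hand arithmetic", {
  fx <- fixture_config(seed = 31, n_branches = 7, noise_sd = 0.05)
  sg <- make_surrogate(make_outlet_set(fx), fx)
  meas <- make_pseudo_measurements(solve_coupled(sg, "present_0d"), fx)
  sg2 <- domain_surrogate(sg$inlet, sg$segments, meas)
  cmp <- compare_variants(sg2)
  tab <- cmp$table[cmp$table$variant == "present_0d", ]
  err_hand <- abs(tab$velocity - tab$measured_velocity) /
    tab$measured_velocity
  expect_equal(tab$rel_error, err_hand, tolerance = 1e-12)
  sm <- cmp$summary[cmp$summary$variant == "present_0d", ]
  expect_equal(sm$mean_error_pct, mean(err_hand) * 100, tolerance = 1e-12)
  expect_equal(sm$sd_error_pct, sd(err_hand) * 100, tolerance = 1e-12)
  # the structured model is closest to measurements generated from itself
  expect_lt(sm$mean_error_pct,
            cmp$summary$mean_error_pct[cmp$summary$variant == "zero_pressure"])
})

test_that("non-convergence raises a structured error carrying the residual history", {
  fx <- fixture_config(seed = 2, n_branches = 7)
  sg <- make_surrogate(make_outlet_set(fx), fx)
  cfg <- run_config(max_iterations = 1)
  err <- tryCatch(solve_coupled(sg, "present_0d", cfg), error = identity)
  expect_s3_class(err, "peritree_no_convergence")
  expect_true(is.numeric(err$residual_history))
})
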
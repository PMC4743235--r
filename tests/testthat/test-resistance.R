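test_that("segment resistance is Poiseuille with length = lambda * radius", {
  set.seed(3)
  for (i in 1:20) {
    r <- runif(1, 1e-5, 5e-3)
    lam <- runif(1, 10, 300)
    mu <- runif(1, 1e-3, 6e-3)
    expect_equal(segment_resistance(r, lam, mu),
                 8 * mu * (lam * r) / (pi * r^4), tolerance = 1e-14)
  }
  # r^3 scaling: halving the radius multiplies resistance by 8
  expect_equal(segment_resistance(5e-4, 30, 4e-3) /
                 segment_resistance(1e-3, 30, 4e-3), 8, tolerance = 1e-12)
  # frozen one-line evaluation
  expect_equal(segment_resistance(6e-4, 16.6667, 0.0046),
               903844694.3804879, tolerance = 1e-12)
  expect_error(segment_resistance(0, 30, 4e-3), "positive")
})

test_that("terminal resistance is pressure over flow", {
  expect_equal(terminal_resistance(mmhg_to_pa(30), 1e-9),
               mmhg_to_pa(30) / 1e-9)
  # homogeneity: doubling the flow halves the resistance
  expect_equal(terminal_resistance(4000, 2e-9),
               terminal_resistance(4000, 1e-9) / 2)
  # the conventional variant closes with zero pressure, zero resistance
  expect_identical(terminal_resistance(0, 1e-9), 0)
  expect_error(terminal_resistance(3999, 0), "positive")
  expect_error(terminal_resistance(-1, 1e-9), "non-negative")
})

test_that("recursion base case: single-level tree with zero terminal resistance", {
  tr <- small_tree(13)
  # truncate to the root level only
  tr1 <- tr
  tr1$levels <- tr$levels[1, ]
  tr1$n_generations <- 0L
  prof <- compute_profile(tr1, 0)
  expect_equal(prof$root_resistance,
               segment_resistance(tr1$levels$radius, tr1$levels$lambda,
                                  tr1$levels$mu_app))
})

test_that("parallel-reduction identity holds at every level", {
  tr <- small_tree(200)
  prof <- compute_profile(tr, 1e12)
  n1 <- length(prof$r_in)
  # 1 / R_out[i-1] = 2 / R_in[i] for symmetric daughters
  expect_equal(1 / prof$r_out[-n1], 2 / prof$r_in[-1], tolerance = 1e-14)
  # a segment always adds resistance
  expect_true(all(prof$r_in > prof$r_out))
  expect_equal(prof$root_resistance, prof$r_in[1])
})

test_that("two-level tree reduces to the hand-derived series/parallel form", {
  tr <- small_tree(13)
  r_seg <- segment_resistance(tr$levels$radius, tr$levels$lambda,
                              tr$levels$mu_app)
  r_term <- 5e11
  by_hand <- r_seg[1] + 0.5 * (r_seg[2] + r_term)
  expect_equal(compute_profile(tr, r_term)$root_resistance, by_hand,
               tolerance = 1e-14)
  expect_equal(explicit_network_resistance(tr, r_term), by_hand,
               tolerance = 1e-14)
})

test_that("recursion agrees with the explicit-network reference on random trees", {
  set.seed(11)
  for (i in 1:50) {
    root_um <- runif(1, 15, 380) # keeps depth within enumeration reach
    tr <- small_tree(root_um)
    expect_lte(tr$n_generations, 15)
    r_term <- runif(1, 0, 1e13)
    expect_equal(compute_profile(tr, r_term)$root_resistance,
                 explicit_network_resistance(tr, r_term),
                 tolerance = 1e-10)
  }
})

test_that("severing one root daughter doubles the sub-root resistance", {
  for (root_um in c(13, 60, 200)) {
    tr <- small_tree(root_um)
    r_seg0 <- segment_resistance(tr$levels$radius[1], tr$levels$lambda[1],
                                 tr$levels$mu_app[1])
    r_sym <- explicit_network_resistance(tr, 1e11)
    r_sev <- explicit_network_resistance(tr, 1e11,
                                         sever_one_root_daughter = TRUE)
    expect_equal(r_sev - r_seg0, 2 * (r_sym - r_seg0), tolerance = 1e-12)
  }
})

test_that("tree depth beyond the enumeration cap is refused", {
  tr <- build_tree(1e-3) # 20 generations
  expect_error(explicit_network_resistance(tr, 0, max_generations = 15),
               "too deep")
})

test_that("terminal fixed point lands on the configured pressure for any root flow", {
  for (r_mm in c(0.3, 1, 2)) {
    for (q in c(1e-8, 1e-6, 1e-4)) {
      tr <- build_tree(r_mm * 1e-3)
      sol <- solve_terminal_fixed_point(tr, q)
      expect_equal(pa_to_mmhg(sol$pressures$p_terminal), 30,
                   tolerance = 1e-9)
    }
  }
  expect_error(solve_terminal_fixed_point(build_tree(1e-3), 0), "positive")
})

test_that("pressure profile marches down consistently and stays monotone", {
  tr <- build_tree(1e-3)
  q <- 1e-6
  sol <- solve_terminal_fixed_point(tr, q)
  p <- sol$pressures$p_inlet
  expect_true(all(diff(p) < 0))
  expect_gt(p[1], sol$pressures$p_terminal)
  # independent chain: p falls by the per-level segment drop
  r_seg <- segment_resistance(tr$levels$radius, tr$levels$lambda,
                              tr$levels$mu_app)
  drops <- (q / 2^tr$levels$index) * r_seg
  p_chain <- p[1] - cumsum(drops[-length(drops)])
  expect_equal(p[-1], p_chain, tolerance = 1e-10)
  # last inlet pressure minus its segment drop is the terminal pressure
  n1 <- nrow(tr$levels)
  expect_equal(p[n1] - drops[n1], sol$pressures$p_terminal,
               tolerance = 1e-9)
  # root pressure referenced to 0 beyond the terminal resistor
  expect_equal(p[1], q * sol$profile$root_resistance, tolerance = 1e-12)
})

test_that("root resistance decreases with outlet radius and is physiologically scaled", {
  radii <- exp(seq(log(0.05e-3), log(5e-3), length.out = 12))
  r_root <- vapply(radii, function(r) {
    compute_profile(build_tree(r), 0)$root_resistance
  }, numeric(1))
  expect_true(all(diff(r_root) < 0))
  # 0.1 mL/s through a millimetre outlet: pressure in the 1e3-1e4 Pa range
  p <- 1e-7 * compute_profile(build_tree(1e-3), 0)$root_resistance
  expect_gt(p, 1e3)
  expect_lt(p, 1e4)
})
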
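test_that("ideal-model trajectories match the closed-form cascade solution", {
  par <- std_params()
  stim <- stimulus_protocol(100, 20, start_time = 40)
  traj <- simulate_ideal(par, stim, dt = 0.05, t_end = 150)
  oracle <- cascade_oracle(17, 4, 1, 100, 20, 40, traj$time)

  rel_err <- function(x, y) max(abs(x - y)) / max(abs(y))
  expect_lt(rel_err(traj$surface, oracle$surface), 1e-4)
  expect_lt(rel_err(traj$alkaline, oracle$alkaline), 1e-4)
  expect_equal(traj$cumulative_exo, oracle$cumulative_exo, tolerance = 1e-10)

  # RK4 fallback agrees with the exact propagator
  traj_rk <- simulate_ideal(par, stim, dt = 0.05, t_end = 150,
                            method = "rk4")
  expect_lt(rel_err(traj_rk$alkaline, traj$alkaline), 1e-5)
})

test_that("no stimulus means empty pools; invalid parameters are rejected", {
  traj <- simulate_ideal(std_params(), stimulus_protocol(0, 20),
                         t_end = 100)
  expect_true(all(traj$surface == 0 & traj$alkaline == 0 &
                    traj$acidified == 0))
  expect_error(kinetic_params(tau_endo = -1), class = "avpdyn_param_error")
  expect_error(kinetic_params(tau_reac = 0), class = "avpdyn_param_error")
  expect_error(simulate_ideal(std_params(), stimulus_protocol(100, 20),
                              dt = -0.1, t_end = 100),
               class = "avpdyn_param_error")
  expect_error(simulate_realistic(std_params(),
                                  stimulus_protocol(100, 20, 40),
                                  cycling_protocol(total_duration = 30)),
               class = "avpdyn_protocol_error")
})

test_that("long stimulation drives A/S to the steady-state ratio tau_reac/tau_endo", {
  par <- std_params()
  stim <- stimulus_protocol(8000, 20, start_time = 0)  # 400 s of drive
  traj <- simulate_ideal(par, stim, dt = 0.05, t_end = 400)
  at_end <- nrow(traj)
  expect_equal(traj$alkaline[at_end] / traj$surface[at_end], 4 / 17,
               tolerance = 1e-3)
})

test_that("mass is conserved on every trajectory (ideal and realistic)", {
  par <- std_params()
  cyc <- std_cycling()
  for (i in seq_len(nrow(std_grid()))) {
    g <- std_grid()[i, ]
    stim <- stimulus_protocol(g$n_ap, g$freq, 40)
    for (traj in list(simulate_ideal(par, stim, t_end = 242),
                      simulate_realistic(par, stim, cyc))) {
      drift <- traj$surface + traj$alkaline + traj$acidified -
        traj$cumulative_exo
      expect_lt(max(abs(drift)), 1e-6 * par$total_release)
      expect_true(all(traj$surface >= -1e-12 & traj$alkaline >= -1e-12 &
                        traj$acidified >= -1e-12))
    }
  }
})

test_that("vanishing acid phases make the realistic model converge to the ideal one", {
  par <- std_params()
  stim <- stimulus_protocol(100, 20, 40)
  cyc <- cycling_protocol(acid_phase_len = 0.001, alkaline_phase_len = 2,
                          cycling_start = 28, total_duration = 120)
  ideal <- simulate_ideal(par, stim, t_end = 120)
  real <- simulate_realistic(par, stim, cyc)
  expect_lt(max(abs(real$alkaline - ideal$alkaline)), 1e-3)
  expect_lt(max(abs(real$surface - ideal$surface)), 1e-3)
})

test_that("pH-cycling can only reduce the detected alkaline peak", {
  par <- std_params()
  cyc <- std_cycling()
  for (i in seq_len(nrow(std_grid()))) {
    g <- std_grid()[i, ]
    stim <- stimulus_protocol(g$n_ap, g$freq, 40)
    ideal <- simulate_ideal(par, stim, t_end = 242)
    real <- simulate_realistic(par, stim, cyc)
    acid <- real$ph_label == "pH5.5"
    expect_lt(max(real$alkaline[acid]), max(ideal$alkaline))
  }
})

test_that("longer alkaline phases preserve more of the alkaline peak", {
  par <- std_params()
  stim <- stimulus_protocol(200, 20, 40)
  fav <- simulate_realistic(par, stim,
                            cycling_protocol(2, 4, 28, 242))
  unfav <- simulate_realistic(par, stim,
                              cycling_protocol(4, 2, 28, 242))
  expect_gt(max(fav$alkaline[fav$ph_label == "pH5.5"]),
            max(unfav$alkaline[unfav$ph_label == "pH5.5"]))
})

test_that("relative alkaline-pool size matches a brute-force maximization of the closed form", {
  par <- std_params()
  stim <- stimulus_protocol(100, 20, 40)
  traj <- simulate_ideal(par, stim, dt = 0.05, t_end = 242)
  got <- relative_avp_size_model(traj)
  dense <- cascade_oracle(17, 4, 1, 100, 20, 40, seq(0, 242, by = 0.005))
  want <- max(dense$alkaline) / max(dense$surface + dense$alkaline)
  expect_equal(got, want, tolerance = 1e-4)

  # instant reacidification empties the alkaline pool
  fast <- simulate_ideal(kinetic_params(17, 1e-3), stim, t_end = 242)
  expect_lt(relative_avp_size_model(fast), 1e-3)

  # no exocytosis: ratio undefined
  empty <- simulate_ideal(par, stimulus_protocol(0, 20), t_end = 100)
  expect_error(relative_avp_size_model(empty),
               class = "avpdyn_param_error")
})

test_that("ideal relative pool size grows with AP number and shrinks with frequency", {
  par <- std_params()
  by_n <- sapply(c(50, 100, 200, 400), function(n)
    relative_avp_size_model(simulate_ideal(par, stimulus_protocol(n, 20, 40),
                                           t_end = 242)))
  expect_true(all(diff(by_n) > 0))
  by_f <- sapply(c(20, 40, 80), function(f)
    relative_avp_size_model(simulate_ideal(par, stimulus_protocol(200, f, 40),
                                           t_end = 242)))
  expect_true(all(diff(by_f) < 0))
})

test_that("reported ratios are grid-converged", {
  par <- std_params()
  stim <- stimulus_protocol(100, 20, 40)
  cyc <- std_cycling()
  r1 <- relative_avp_size_model(simulate_realistic(par, stim, cyc,
                                                   dt = 0.05))
  r2 <- relative_avp_size_model(simulate_realistic(par, stim, cyc,
                                                   dt = 0.025))
  expect_lt(abs(r1 - r2), 1e-4)
})

test_that("pH-cycling underestimation behaves as expected", {
  par <- std_params()
  stim <- stimulus_protocol(100, 20, 40)
  # near-vanishing acid phases (one sampled frame each): underestimation
  # shrinks towards zero with the acid exposure
  tiny <- cycling_protocol(0.05, 2, 28, 120)
  expect_lt(underestimation(par, stim, tiny), 0.05)
  # more acid time, more underestimation
  u_fav <- underestimation(par, stim, cycling_protocol(2, 4, 28, 242))
  u_unfav <- underestimation(par, stim, cycling_protocol(4, 2, 28, 242))
  expect_gt(u_unfav, u_fav)
})

test_that("surface fluorescence fraction reproduces the quench arithmetic", {
  expect_equal(surface_fluorescence_fraction(0.24, 20),
               0.24 / (0.24 + 0.76 / 20))
  # the two markers' printed values: about 86% and about 38%
  expect_equal(round(100 * surface_fluorescence_fraction(0.24, 20)), 86)
  expect_equal(round(100 * surface_fluorescence_fraction(0.03, 20)), 38)
  expect_equal(surface_fluorescence_fraction(1, 7), 1)
  expect_error(surface_fluorescence_fraction(1.2, 20),
               class = "avpdyn_param_error")
  expect_error(surface_fluorescence_fraction(0.5, 0.5),
               class = "avpdyn_param_error")
})
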
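test_that("somatic right-hand side matches hand-evaluated cases", {
  p <- list(Cm = 100, gL = 5, EL = -70, E_A = -70, V_A = -70,
            gbar_A = 2, tau_A = 100)
  # rest is a fixed point
  expect_equal(soma_rhs(-70, 0, p)[["dV"]], 0)
  # 100 pA into 100 pF from rest: 1 mV/ms
  expect_equal(soma_rhs(-70, 0, p, I_ext = 100)[["dV"]], 1)
  # at V = V_A the adaptation drive vanishes
  expect_equal(soma_rhs(-70, 3, p)[["dgA"]], -3 / 100)
})

test_that("dendritic right-hand side matches hand-evaluated cases", {
  p <- list(Cm = 50, gL = 2, EL = -70, E_Na = 70, E_K = -89,
            tau_Na = 1.5, tau_Kdr = 3)
  # without spike conductances it reduces to the passive membrane
  expect_equal(dendrite_rhs(-60, 0, 0, p)[["dV"]],
               -2 * (-60 + 70) / 50)
  # g_Na = 10 nS at -60 mV: +1300 pA depolarizing
  r <- dendrite_rhs(-60, 10, 0, p)
  I_na <- -10 * (-60 - 70)
  expect_equal(I_na, 1300)
  expect_equal(r[["dV"]], (-2 * 10 + 1300) / 50)
  expect_equal(r[["dgNa"]], -10 / 1.5)
})

test_that("axial currents are pairwise antisymmetric and sum to zero", {
  m <- chain_model()
  # equal voltages: no axial current anywhere
  expect_equal(axial_currents(m, rep(-63, 4)), rep(0, 4))

  m2 <- two_comp()
  g <- m2$W["soma", "dend"]
  I <- axial_currents(m2, c(-60, -70))
  expect_equal(I[2], g * 10)   # into the hyperpolarized compartment
  expect_equal(I[1], -g * 10)

  set.seed(3)
  for (i in 1:20) {
    V <- runif(4, -90, 0)
    expect_equal(sum(axial_currents(m, V)), 0, tolerance = 1e-12)
  }
})

test_that("the two-stage somatic reset follows the printed rules", {
  cc <- compartment("soma", "soma", 20, 20, spine_factor = 1)
  m <- neuron_model(list(cc),
                    soma = soma_params(V_th = -50, V_spike = 40,
                                       V_reset = -55, reset_delay = 0.5,
                                       b = 3, gbar_A = 0, tau_A = 100))
  sim <- simulate_model(m, list(stim_step("soma", 400)), duration = 30,
                        dt = 0.1, record = c("V", "gA"))
  ev <- sim$events
  spikes <- ev[ev$event == "soma_spike", ]
  resets <- ev[ev$event == "soma_reset", ]
  expect_gt(nrow(spikes), 0)
  # every spike is followed by a reset exactly reset_delay later
  expect_equal(resets$time[1], spikes$time[1] + 0.5)
  # an event at time t acts on the step [t, t + dt): the first recorded
  # sample after the spike shows the V_spike plateau, the first sample
  # after the delayed event shows the reset (plus one step of drift)
  i_spk <- which(abs(sim$time - spikes$time[1]) < 1e-9)
  i_rst <- which(abs(sim$time - resets$time[1]) < 1e-9)
  expect_equal(unname(sim$V[i_spk + 1, "soma"]), 40, tolerance = 0.01)
  # the plateau persists until the reset
  expect_true(all(sim$V[(i_spk + 1):i_rst, "soma"] > 35))
  expect_lt(abs(sim$V[i_rst + 1, "soma"] - (-55)), 5)
  # the plateau suppresses retriggering: no two spikes closer than the
  # reset delay, and the adaptation increment b is applied exactly once
  # per spike (g_A just after the first spike = b, minus one step of decay)
  expect_true(all(diff(spikes$time) > 0.5 - 1e-9))
  expect_equal(sim$gA[i_spk + 1], 3, tolerance = 0.01)
})

test_that("dendritic spike events follow the two-flag state machine", {
  m <- dspike_model(t_ref = 5, t_offset = 2)
  # hold the dendrite above threshold with a strong constant current
  sim <- simulate_model(m, list(stim_step("dend", 500)), duration = 40,
                        dt = 0.1, record = "none")
  ev <- sim$events[sim$events$compartment == "dend", ]
  na <- ev$time[ev$event == "dspike_na"]
  kdr <- ev$time[ev$event == "dspike_kdr"]
  expect_gt(length(na), 2)
  # repetitive firing at the refractory limit: the strict inequality puts
  # successive events one grid step beyond the refractory period
  expect_equal(diff(na), rep(5 + 0.1, length(na) - 1), tolerance = 1e-9)
  # each K event lands on the first grid time strictly after t_na + offset
  expect_equal(kdr[seq_along(na)] - na, rep(2 + 0.1, length(na)),
               tolerance = 1e-9)
  # strict alternation of Na and K events (flag exclusivity)
  ord <- ev[order(ev$time), "event"]
  expect_true(all(ord == rep(c("dspike_na", "dspike_kdr"),
                             length.out = length(ord))))
})

test_that("threshold crossing alone does not fire a disarmed mechanism", {
  m <- dspike_model(enabled = FALSE)
  sim <- simulate_model(m, list(stim_step("dend", 500)), duration = 20,
                        dt = 0.1, record = "none")
  expect_equal(nrow(sim$events), 0L)
})

test_that("a disabled mechanism is trace-identical to an absent one", {
  m_dis <- set_dspikes(dspike_model(with_params = TRUE), FALSE)
  m_none <- dspike_model(with_params = FALSE)
  s1 <- simulate_model(m_dis, list(stim_step("dend", 300)), duration = 50,
                       dt = 0.1)
  s2 <- simulate_model(m_none, list(stim_step("dend", 300)), duration = 50,
                       dt = 0.1)
  expect_lt(max(abs(s1$V - s2$V)), 1e-9)
})

test_that("spike conductances stay non-negative and refractoriness holds
          under random synaptic bombardment", {
  m <- model_active_4c()
  stims <- list(stim_poisson(c("distal_ampa", "distal_nmda"), 80),
                stim_poisson(c("proximal_ampa", "proximal_nmda"), 80))
  sim <- simulate_model(m, stims, duration = 400, dt = 0.1, seed = 99,
                        record = c("gNa", "gKdr"))
  expect_true(all(sim$gNa >= 0))
  expect_true(all(sim$gKdr >= 0))
  ev <- sim$events
  for (cc in c("trunk", "proximal", "distal")) {
    na <- sort(ev$time[ev$event == "dspike_na" & ev$compartment == cc])
    if (length(na) > 1)
      expect_true(all(diff(na) > 5))  # t_ref_Na of the fixture
    # alternation: between two Na events there is exactly one K event
    kdr <- sort(ev$time[ev$event == "dspike_kdr" & ev$compartment == cc])
    expect_true(abs(length(na) - length(kdr)) <= 1)
  }
})

test_that("parameter validation rejects inconsistent event timing", {
  expect_error(dspike_params(10, 6, t_ref_Na = 2, t_offset_Kdr = 3),
               "t_offset_Kdr")
  expect_error(soma_params(V_th = -50, V_spike = -60, V_reset = -70),
               "V_spike")
})
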
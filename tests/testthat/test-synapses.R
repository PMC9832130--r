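test_that("dual-exponential peak time and normalization", {
  pk <- syn_peak_norm(2, 10)
  expect_equal(unname(pk["t_peak"]), 4.0236, tolerance = 1e-4)
  expect_equal(unname(pk["f_syn"]), 1.8692, tolerance = 1e-4)
  # f_syn * s(t_peak) = 1 for any valid pair
  set.seed(11)
  for (i in 1:50) {
    tr <- runif(1, 0.1, 20); td <- tr * runif(1, 1.05, 50)
    pk <- syn_peak_norm(tr, td)
    s_pk <- exp(-pk["t_peak"] / td) - exp(-pk["t_peak"] / tr)
    expect_equal(unname(pk["f_syn"] * s_pk), 1, tolerance = 1e-12)
  }
  # decay >> rise: the waveform approaches pure decay with unit peak
  expect_equal(unname(syn_peak_norm(1, 1e6)["f_syn"]), 1, tolerance = 1e-3)
  expect_error(syn_peak_norm(5, 5), "invalid kinetics")
  expect_error(synapse_params("AMPA", 1, "x", tau_rise = 3, tau_decay = 3),
               "invalid kinetics")
})

test_that("closed-form waveforms respect the Heaviside gate and limits", {
  sp <- synapse_params("AMPA", gbar = 1, name = "a", tau_rise = 2,
                       tau_decay = 10)
  expect_equal(closed_form_waveform(sp, c(-5, 9.9), t_pre = 10), c(0, 0))
  expect_equal(closed_form_waveform(sp, 10, t_pre = 10), 0)
  se <- synapse_params("AMPA", gbar = 1, name = "a", tau_decay = 3,
                       kinetics = "single_exp")
  expect_equal(closed_form_waveform(se, 10, t_pre = 10), 1)
})

test_that("normalized dual-exponential peak equals one across random taus", {
  set.seed(4)
  for (i in 1:200) {
    tr <- runif(1, 0.1, 15); td <- tr * runif(1, 1.02, 40)
    sp <- synapse_params("AMPA", gbar = 1, name = "a", tau_rise = tr,
                         tau_decay = td)
    # numeric maximization oracle, independent of the peak-time formula
    pk <- stats::optimize(function(t)
      closed_form_waveform(sp, t, normalized = TRUE),
      interval = c(0, 40 * td), maximum = TRUE, tol = 1e-10)$objective
    expect_equal(pk, 1, tolerance = 1e-6)
  }
})

test_that("magnesium block has the right value, limits and monotonicity", {
  mg <- mg_params()
  expect_equal(mg_sigma(mg, 0), 0.7812, tolerance = 1e-4)
  # V = gamma: sigma = 1/(1 + Mg/beta)
  mg2 <- mg_params(gamma = -10, mg_out = 2, beta = 4)
  expect_equal(mg_sigma(mg2, -10), 1 / (1 + 2 / 4))
  expect_equal(mg_sigma(mg, 1e4), 1)
  # strictly increasing in V
  V <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(mg_sigma(mg, V)) > 0))
})

test_that("single-exponential ODE kinetics superpose like the closed form", {
  sp <- synapse_params("AMPA", gbar = 1, name = "a", tau_decay = 6,
                       kinetics = "single_exp")
  # no spikes: stays at zero
  st <- c(s = 0, x = 0)
  for (i in 1:100) st <- kinetics_step(sp, st, 0.05)
  expect_equal(unname(st["s"]), 0)
  # one spike, read after a delay: exact exponential (exact integrator not
  # needed; compare against the closed form with a fine step)
  st <- on_presyn_spike(sp, c(s = 0, x = 0))
  dt <- 1e-4
  for (i in seq_len(2 / dt)) st <- kinetics_step(sp, st, dt)
  expect_equal(unname(st["s"]), exp(-2 / 6), tolerance = 1e-4)
  # superposition for an arbitrary spike train
  spikes <- c(0, 0.7, 1.3, 4.2)
  st <- c(s = 0, x = 0); t <- 0
  repeat {
    if (any(abs(t - spikes) < dt / 2)) st <- on_presyn_spike(sp, st)
    if (t >= 6) break
    st <- kinetics_step(sp, st, dt); t <- t + dt
  }
  expect_equal(unname(st["s"]), sum(exp(-(6 - spikes) / 6)),
               tolerance = 1e-3)
})

test_that("saturating dual-exponential state stays in [0, 1]", {
  sp <- synapse_params("AMPA", gbar = 1, name = "a", tau_rise = 0.5,
                       tau_decay = 4)
  set.seed(21)
  for (rep in 1:5) {
    st <- c(s = 0, x = 0)
    spikes <- sort(runif(80, 0, 20))
    t <- 0; dt <- 0.01; smax <- 0
    while (t < 25) {
      nsp <- sum(spikes >= t & spikes < t + dt)
      if (nsp) st["x"] <- st["x"] + nsp
      st <- kinetics_step(sp, st, dt)
      smax <- max(smax, st["s"])
      expect_gte(st[["s"]], 0)
      t <- t + dt
    }
    expect_lte(smax, 1)
  }
})

test_that("dual-exponential ODE peaks near the closed-form peak time", {
  sp <- synapse_params("AMPA", gbar = 1, name = "a", tau_rise = 2,
                       tau_decay = 10)
  st <- c(s = 0, x = 0.01)  # small amplitude: saturation negligible
  dt <- 1e-3; t <- 0; best <- c(0, 0)
  while (t < 30) {
    st <- kinetics_step(sp, st, dt); t <- t + dt
    if (st["s"] > best[2]) best <- c(t, st[["s"]])
  }
  expect_equal(best[1], unname(syn_peak_norm(sp)["t_peak"]),
               tolerance = 0.05)
})

test_that("compartment synaptic current sums, reverses and scales", {
  a <- synapse_params("AMPA", gbar = 1, name = "a")
  expect_equal(compartment_synaptic_current(list(a), 0, -70), 0)
  # with s*f = 1: I = -gbar (V - E) = 70 pA depolarizing at -70 mV
  s_unit <- 1 / unname(syn_peak_norm(a)["f_syn"])
  expect_equal(compartment_synaptic_current(list(a), s_unit, -70), 70)
  expect_equal(compartment_synaptic_current(list(a), s_unit, 0), 0)
  # linear in gbar and in the number of identical co-active instances
  a5 <- synapse_params("AMPA", gbar = 5, name = "a5")
  expect_equal(compartment_synaptic_current(list(a5), s_unit, -70),
               5 * compartment_synaptic_current(list(a), s_unit, -70))
  expect_equal(
    compartment_synaptic_current(list(a, a, a), rep(s_unit, 3), -70),
    3 * compartment_synaptic_current(list(a), s_unit, -70))
})

test_that("synapse declaration rules are enforced", {
  expect_error(synapse_params("AMPA", 1, "x", mg = mg_params()),
               "NMDA")
  sp <- synapse_params("NMDA", 1, "n")
  expect_s3_class(sp$mg, "mg_params")
})
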
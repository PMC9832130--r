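test_that("rest is preserved and sample counting is exact", {
  m <- two_comp()
  sim <- simulate_model(m, duration = 1, dt = 0.1)
  expect_length(sim$time, 11L)
  expect_true(all(sim$V == -70))
})

test_that("passive step response matches the closed form", {
  m <- one_comp()                      # Cm 100 pF, gL 5 nS, tau 20 ms
  sim <- simulate_model(m, list(stim_step("soma", 100)), duration = 100,
                        dt = 0.01, method = "rk4")
  tau <- 20; R <- 1 / 5  # GOhm
  exact <- -70 + 100 * R * (1 - exp(-sim$time / tau))
  expect_lt(max(abs(sim$V[, 1] - exact)) / (100 * R), 0.005)
})

test_that("two coupled compartments reach the analytic steady state", {
  m <- two_comp()
  sim <- simulate_model(m, list(stim_step("soma", -10)), duration = 800,
                        dt = 0.1)
  vss <- passive_steady_state(m, c(-10, 0))
  v_end <- sim$V[nrow(sim$V), ]
  expect_lt(max(abs(v_end - vss) / abs(vss - (-70))), 0.005)
})

test_that("explicit integrators agree and converge at their orders", {
  m <- one_comp()
  final_v <- function(dt, method)
    simulate_model(m, list(stim_step("soma", 100)), duration = 50,
                   dt = dt, method = method, record_stride = ceiling(1 / dt)
    )$V |> tail(1) |> as.numeric()
  exact <- -70 + 20 * (1 - exp(-50 / 20))
  # cross-method agreement at small dt
  expect_lt(abs(final_v(0.01, "euler") - final_v(0.01, "rk4")) /
              abs(exact + 70), 0.001)
  # convergence order by log-2 error ratios over dt = 0.1, 0.05, 0.025
  err <- function(method) vapply(c(0.1, 0.05, 0.025), function(dt)
    abs(final_v(dt, method) - exact), numeric(1))
  ord <- function(e) mean(log2(e[-length(e)] / e[-1]))
  expect_equal(ord(err("euler")), 1, tolerance = 0.25)
  expect_gt(ord(err("rk4")), 3.2)
  expect_equal(ord(err("rk2")), 2, tolerance = 0.4)
})

test_that("trajectories match an independent stiff ODE solver", {
  # two-compartment passive model with a synapse, integrated independently
  # with deSolve's implicit lsoda as the oracle
  comps <- list(
    compartment("soma", "soma", 20, 20, spine_factor = 1),
    compartment("dend", "dendrite", 200, 2, spine_factor = 1,
                synapses = list(synapse_params("AMPA", gbar = 2,
                                               name = "syn",
                                               tau_rise = 1,
                                               tau_decay = 8))))
  m <- neuron_model(comps, list(c("soma", "dend")),
                    soma = soma_params(V_th = 1e3, V_spike = 1e3 + 1,
                                       V_reset = 990))
  sim <- simulate_model(m, list(stim_spikes("syn", 5),
                                stim_step("soma", 20, onset = 0)),
                        duration = 60, dt = 0.01, method = "rk4")

  g <- m$W[1, 2]; gL <- m$gL; Cm <- m$Cm
  f <- m$syn$f_syn * m$syn$gbar
  rhs <- function(t, y, parms) {
    I_syn <- -f * y["s"] * (y["v2"] - 0)
    dv1 <- (-gL[1] * (y["v1"] + 70) + g * (y["v2"] - y["v1"]) + 20) / Cm[1]
    dv2 <- (-gL[2] * (y["v2"] + 70) + g * (y["v1"] - y["v2"]) + I_syn) / Cm[2]
    ds <- -y["s"] / 8 + y["x"] * (1 - y["s"]) / 1
    dx <- -y["x"] / 1
    list(c(dv1, dv2, dx, ds))
  }
  # lsoda with an event adding 1 to x at t = 5
  ev <- data.frame(var = "x", time = 5, value = 1, method = "add")
  out <- deSolve::lsoda(c(v1 = -70, v2 = -70, x = 0, s = 0),
                        times = sim$time, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12,
                        events = list(data = ev))
  expect_lt(max(abs(sim$V[, "soma"] - out[, 2])), 0.01)
  expect_lt(max(abs(sim$V[, "dend"] - out[, 3])), 0.01)
})

test_that("simulations are reproducible bit for bit", {
  m <- model_ca1_9c()
  st <- list(stim_poisson(c("tuft1_ampa", "tuft1_nmda"), 30),
             stim_noise("soma", 0, 20))
  s1 <- simulate_model(m, st, duration = 200, dt = 0.1, n = 5, seed = 123)
  s2 <- simulate_model(m, st, duration = 200, dt = 0.1, n = 5, seed = 123)
  expect_identical(s1$V, s2$V)
  expect_identical(s1$events, s2$events)
  # adding a stimulus does not perturb the realizations of earlier ones
  s3 <- simulate_model(m, c(st, list(stim_poisson("oblique1_ampa", 10))),
                       duration = 200, dt = 0.1, n = 5, seed = 123)
  ev_tuft <- function(s) s$events[s$events$compartment == "tuft1", ]
  expect_identical(ev_tuft(s1), ev_tuft(s3))
})

test_that("stochastic stimuli demand a seed and match their moments", {
  m <- one_comp()
  expect_error(simulate_model(m, list(stim_noise("soma", 0, 5)),
                              duration = 10),
               "seed")
  # Poisson train: mean count across seeds within 3 s.e.
  counts <- vapply(1:500, function(s)
    length(poisson_train(20, 10000, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200 / 500))
  expect_identical(poisson_train(20, 1000, seed = 7),
                   poisson_train(20, 1000, seed = 7))
  expect_identical(poisson_train(0, 1000), numeric(0))
  # synchronous train arithmetic
  expect_equal(synchronous_train(1, t0 = 3), 3)
  expect_equal(synchronous_train(5, 0.1, 100),
               c(100, 100.1, 100.2, 100.3, 100.4))
  # Gaussian noise moments (per-step values)
  sim <- simulate_model(one_comp(), list(stim_noise("soma", 2, 5)),
                        duration = 2000, dt = 0.1, seed = 5,
                        record = "none")
  # recover the injected sequence is indirect; test the generator through
  # a long trace of dV instead: mean current = Cm dV/dt + gL (V - EL)
  sim2 <- simulate_model(one_comp(), list(stim_noise("soma", 2, 5)),
                         duration = 2000, dt = 0.1, seed = 5)
  v <- sim2$V[, 1]
  I_rec <- 100 * diff(v) / 0.1 + 5 * (v[-length(v)] + 70)
  expect_lt(abs(mean(I_rec) - 2), 3 * 5 / sqrt(length(I_rec)))
  expect_lt(abs(sd(I_rec) - 5), 0.5)
})

test_that("numerical blow-up aborts with a located diagnostic", {
  # a tiny stub tightly coupled to a large soma is stiff far beyond the
  # forward-Euler stability limit
  comps <- list(compartment("soma", "soma", 20, 20, spine_factor = 1),
                compartment("stub", "dendrite", 1, 1, spine_factor = 1))
  m <- neuron_model(comps, list(c("soma", "stub")),
                    soma = soma_params(V_th = 1e3, V_spike = 1e3 + 1,
                                       V_reset = 990))
  expect_error(
    suppressWarnings(simulate_model(m, list(stim_step("soma", 500)),
                                    duration = 50, dt = 0.1)),
    "non-finite voltage")
})

test_that("a large integration step triggers a warning", {
  w <- capture_warnings(simulate_model(one_comp(), duration = 5, dt = 0.5))
  expect_true(any(grepl("0.1 ms", w)))          # accuracy regime
  expect_true(any(grepl("event delay", w)))     # coarse event rounding
})
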
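test_that("cylinder area follows the open-cylinder formula", {
  expect_equal(cylinder_area(1, 1), pi * 1e-8)
  expect_equal(cylinder_area(100, 2), 6.28319e-6, tolerance = 1e-6)
  # bilinearity: doubling both dimensions quadruples the area
  expect_equal(cylinder_area(200, 4), 4 * cylinder_area(100, 2))
  expect_error(cylinder_area(0, 1), "invalid geometry")
  expect_error(cylinder_area(10, -1), "invalid geometry")
})

test_that("absolute passive properties and their invariants", {
  cc <- compartment("d", "dendrite", 100, 2, cm_uF_cm2 = 1,
                    rm_kOhm_cm2 = 20, spine_factor = 1)
  ap <- absolute_passive(cc)
  expect_equal(unname(ap["Cm_pF"]), 6.28319, tolerance = 1e-6)
  expect_equal(unname(ap["gL_nS"]), 0.314159, tolerance = 1e-6)

  # tau_m = Cm/gL = cm*rm independent of geometry and spine factor
  for (i in 1:20) {
    set.seed(i)
    l <- runif(1, 5, 500); d <- runif(1, 0.3, 30)
    sf <- runif(1, 1, 2); cm <- runif(1, 0.5, 3); rm <- runif(1, 5, 50)
    cc <- compartment("d", "dendrite", l, d, cm_uF_cm2 = cm,
                      rm_kOhm_cm2 = rm, spine_factor = sf)
    ap <- absolute_passive(cc)
    tau <- ap["Cm_pF"] / ap["gL_nS"]          # ms
    expect_equal(unname(tau), cm * rm, tolerance = 1e-12)
  }

  # the spine factor scales both outputs linearly
  c1 <- compartment("d", "dendrite", 100, 2, spine_factor = 1)
  c15 <- compartment("d", "dendrite", 100, 2, spine_factor = 1.5)
  expect_equal(absolute_passive(c15), 1.5 * absolute_passive(c1))
})

test_that("coupling conductance matches hand-computed values", {
  a <- compartment("a", "dendrite", 100, 1, ra_Ohm_cm = 150,
                   spine_factor = 1)
  b <- compartment("b", "dendrite", 200, 2, ra_Ohm_cm = 150,
                   spine_factor = 1)
  # full cylinder on the distal compartment: R = 190.986 MOhm
  g_full <- coupling_conductance(b, a, "full_cylinder")
  expect_equal(g_full, 5.2360, tolerance = 1e-4)
  expect_equal(1e3 / g_full, 190.986, tolerance = 1e-5)  # MOhm

  # identical compartments: half-cylinder equals full-cylinder
  expect_equal(coupling_conductance(a, a, "half_cylinder"),
               coupling_conductance(a, a, "full_cylinder"))

  # mixed geometry, half-cylinder: R = 143.239 MOhm -> 6.9813 nS
  g_half <- coupling_conductance(a, b, "half_cylinder")
  expect_equal(g_half, 6.9813, tolerance = 1e-4)

  # half-cylinder coupling is invariant under swapping the compartments
  expect_identical(coupling_conductance(a, b), coupling_conductance(b, a))
})

test_that("coupling conductance is monotone in diameter and length", {
  set.seed(7)
  for (i in 1:50) {
    l <- runif(1, 10, 400); d <- runif(1, 0.5, 10)
    base <- compartment("x", "dendrite", l, d, spine_factor = 1)
    wider <- compartment("x", "dendrite", l, d * runif(1, 1.01, 3),
                         spine_factor = 1)
    longer <- compartment("x", "dendrite", l * runif(1, 1.01, 3), d,
                          spine_factor = 1)
    ref <- compartment("r", "dendrite", 100, 2, spine_factor = 1)
    expect_gt(coupling_conductance(wider, ref),
              coupling_conductance(base, ref))
    expect_lt(coupling_conductance(longer, ref),
              coupling_conductance(base, ref))
  }
})

test_that("model assembly validates the compartment graph", {
  mk <- function(n) compartment(paste0("c", n), "dendrite", 100, 1)
  soma <- compartment("soma", "soma", 20, 20)

  # cycle / wrong edge count
  expect_error(
    neuron_model(list(soma, mk(1), mk(2)),
                 list(c("soma", "c1"), c("c1", "c2"), c("c2", "soma"))),
    "tree")
  # disconnected
  expect_error(
    neuron_model(list(soma, mk(1), mk(2)),
                 list(c("soma", "c1"), c("soma", "c1"))),
    "tree|self-edge|disconnected")
  # duplicate names
  expect_error(neuron_model(list(soma, mk(1), mk(1)),
                            list(c("soma", "c1"), c("c1", "c1"))),
               "duplicate")
  # soma count
  expect_error(neuron_model(list(mk(1), mk(2)), list(c("c1", "c2"))),
               "exactly one soma")
  expect_error(
    neuron_model(list(soma, compartment("s2", "soma", 20, 20)),
                 list(c("soma", "s2"))),
    "exactly one soma")
})

test_that("a five-compartment pyramidal skeleton assembles correctly", {
  comps <- list(
    compartment("soma", "soma", 20, 20),
    compartment("basal", "dendrite", 150, 1.5),
    compartment("trunk_prox", "dendrite", 100, 2.5),
    compartment("trunk_dist", "dendrite", 150, 2),
    compartment("tuft", "dendrite", 100, 1))
  m <- neuron_model(comps,
                    list(c("soma", "basal"), c("soma", "trunk_prox"),
                         c("trunk_prox", "trunk_dist"),
                         c("trunk_dist", "tuft")))
  expect_s3_class(m, "neuron_model")
  expect_equal(m$n_comp, 5L)
  # symmetric coupling matrix with one nonzero pair per edge
  expect_identical(m$W, t(m$W))
  expect_equal(sum(m$W > 0), 2L * 4L)
})

test_that("coupling overrides replace edge conductances symmetrically", {
  comps <- list(compartment("soma", "soma", 20, 20),
                compartment("d", "dendrite", 100, 1))
  m <- neuron_model(comps, list(c("soma", "d")),
                    coupling_overrides = list("soma|d" = 7.5))
  expect_equal(m$W["soma", "d"], 7.5)
  expect_identical(m$W["soma", "d"], m$W["d", "soma"])
  expect_error(
    neuron_model(comps, list(c("soma", "d")),
                 coupling_overrides = list("soma|x" = 1)),
    "override")
})

test_that("blocking a receptor kind zeroes its conductances only", {
  m <- model_passive_3c()
  mb <- block_synapses(m, "NMDA")
  expect_equal(mb$syn$gbar[mb$syn$kind == "NMDA"], 0)
  expect_equal(mb$syn$gbar[mb$syn$kind == "AMPA"],
               m$syn$gbar[m$syn$kind == "AMPA"])
})
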
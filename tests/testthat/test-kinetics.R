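# Convenience kinetics: closed forms, limits, regulation, scaling,
# monotonicity.

test_that("irreversible single-substrate kinetics equals Michaelis-Menten", {
  m <- single_reaction_model(kcat = 2, Km = 1)
  # half saturation: kcat/2
  expect_equal(specific_rate(m, "t", a = 1, c = c(1, 1)), 1)
  # saturation limit
  expect_equal(specific_rate(m, "t", a = 1e12, c = c(1, 1)), 2,
               tolerance = 1e-9)
  # full curve, 1000 points, 1e-12 relative
  x <- 10^seq(-6, 6, length.out = 1000)
  rates <- vapply(x, function(xi) specific_rate(m, "t", a = xi, c = c(1, 1)),
                  numeric(1))
  expect_equal(rates, 2 * x / (1 + x), tolerance = 1e-12)
})

test_that("turnover time is the reciprocal rate with the product form", {
  m <- single_reaction_model(kcat = 2, Km = 1)
  expect_equal(turnover_time(m, "t", a = 1, c = c(1, 1)), 1)
  # two substrates, both saturated: tau -> 1/kcat
  mm <- chain3_model(10, 1, 10, 1, 10, 1, 300, 5)$model
  expect_equal(turnover_time(mm, "e1", a = 5, c = c(1e9, 1e9, 1)),
               1 / 10, tolerance = 1e-8)
})

test_that("activation at c = KA doubles tau; inhibition at c = KI doubles tau", {
  base <- single_reaction_model(kcat = 2, Km = 1)
  act <- single_reaction_model(kcat = 2, Km = 1, KA = 3)
  inh <- single_reaction_model(kcat = 2, Km = 1, KI = 3)
  tau0 <- turnover_time(base, "t", a = 1, c = c(3, 1))
  expect_equal(turnover_time(act, "t", a = 1, c = c(3, 1)), 2 * tau0)
  expect_equal(turnover_time(inh, "t", a = 1, c = c(3, 1)), 2 * tau0)
  # explicit product form: (1/kcat)(1 + K/a)(1 + KA/c)
  expect_equal(turnover_time(act, "t", a = 4, c = c(6, 1)),
               (1 / 2) * (1 + 1 / 4) * (1 + 3 / 6))
})

test_that("reversible rate vanishes at the numerator root and goes negative beyond", {
  # kcat_f (x/Ks) = kcat_b (p/Kp): equilibrium composition
  m <- single_reaction_model(kcat = 2, Km = 1, reversible_kcat_b = 1, K_prod = 2)
  # x/1 * 2 = p/2 * 1  =>  p = 4x
  expect_equal(specific_rate(m, "t", a = 1, c = c(4, 1)), 0, tolerance = 1e-12)
  expect_lt(specific_rate(m, "t", a = 1, c = c(8, 1)), 0)
  expect_gt(specific_rate(m, "t", a = 1, c = c(2, 1)), 0)
})

test_that("regulation factor stays in (0, 1] and equals 1 without regulation", {
  set.seed(4)
  for (i in 1:50) {
    KA <- runif(1, 0.1, 10); KI <- runif(1, 0.1, 10)
    m <- single_reaction_model(kcat = 2, Km = 1, KA = KA, KI = KI)
    base <- single_reaction_model(kcat = 2, Km = 1)
    cC <- runif(1, 1e-6, 100)
    ratio <- specific_rate(m, "t", a = 1, c = c(cC, 1)) /
      specific_rate(base, "t", a = 1, c = c(cC, 1))
    expect_gt(ratio, 0)
    expect_lte(ratio, 1)
  }
})

test_that("kcat scaling multiplies rates and divides tau (property)", {
  gm <- generate_model(model_spec(n_rxn = 6, seed = 21,
                                  reversible_fraction = 0.5,
                                  regulation_density = 0.5))
  m <- gm$model
  set.seed(9)
  for (lambda in c(0.5, 2, 10)) {
    ms <- m
    ms$kcat_f <- m$kcat_f * lambda
    ms$kcat_b <- m$kcat_b * lambda
    a <- runif(m$n_ext, 0.1, 50)
    cc <- runif(nrow(m$M) - m$n_ext, 0.1, 100)
    for (j in seq_len(ncol(m$M))) {
      r0 <- specific_rate(m, j, a, cc)
      expect_equal(specific_rate(ms, j, a, cc), lambda * r0, tolerance = 1e-12)
    }
  }
})

test_that("irreversible rates are monotone in substrates, activators, inhibitors", {
  m <- single_reaction_model(kcat = 5, Km = 2, KA = 1, KI = 4)
  set.seed(17)
  for (i in 1:30) {
    a <- runif(1, 1e-3, 50); cC <- runif(1, 1e-3, 50)
    h <- 1e-4
    r <- function(a_, c_) specific_rate(m, "t", a = a_, c = c(c_, 1))
    expect_gte(r(a + h, cC), r(a, cC))   # substrate up, rate up
    # c acts as both activator and inhibitor here; test them separately
    act_only <- single_reaction_model(kcat = 5, Km = 2, KA = 1)
    inh_only <- single_reaction_model(kcat = 5, Km = 2, KI = 4)
    ra <- function(c_) specific_rate(act_only, "t", a = a, c = c(c_, 1))
    ri <- function(c_) specific_rate(inh_only, "t", a = a, c = c(c_, 1))
    expect_gte(ra(cC + h), ra(cC))
    expect_lte(ri(cC + h), ri(cC))
  }
})

test_that("protein demand follows p = v * tau with sign semantics", {
  m <- single_reaction_model(kcat = 2, Km = 1)
  expect_equal(protein_demand(m, "t", v_alpha = 0, a = 1, c = c(1, 1)), 0)
  expect_equal(protein_demand(m, "t", v_alpha = 3, a = 1, c = c(1, 1)), 3)
  # reversible backward-favored context: positive flux demands negative
  # protein, an infeasibility marker
  mr <- single_reaction_model(kcat = 2, Km = 1, reversible_kcat_b = 1, K_prod = 2)
  expect_lt(protein_demand(mr, "t", v_alpha = 1, a = 1, c = c(8, 1)), 0)
})

test_that("zero concentrations are clamped, keeping evaluation total", {
  m <- single_reaction_model(kcat = 2, Km = 1)
  r <- specific_rate(m, "t", a = 0, c = c(0, 0))
  expect_true(is.finite(r))
  expect_gte(r, 0)
  expect_true(is.infinite(turnover_time(m, "t", a = 0, c = c(0, 0))) ||
                turnover_time(m, "t", a = 0, c = c(0, 0)) > 1e11)
})
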
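# Growth program assembly and the NLP solver.

test_that("growth_rate matches the closed-form minimal-model reduction", {
  p <- random_params(3)
  mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, p$a)
  cond <- condition_slice(mm$conditions, 1)
  or <- oracle_minimal(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, p$a)
  for (xr in c(1, 0.3 * p$rho, 0.8 * p$rho)) {
    expect_equal(growth_rate(mm$model, cond, xi = c(p$rho, xr)),
                 or$mu_fun(xr), tolerance = 1e-10)
  }
  # no protein production: mu = 0
  expect_equal(growth_rate(mm$model, cond, xi = c(p$rho, 0)), 0)
})

test_that("doubling every kcat doubles mu at fixed xi", {
  p <- random_params(5)
  mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, p$a)
  m2 <- mm$model
  m2$kcat_f <- m2$kcat_f * 2
  cond <- condition_slice(mm$conditions, 1)
  xi <- c(p$rho, 0.5 * p$rho)
  expect_equal(growth_rate(m2, cond, xi), 2 * growth_rate(mm$model, cond, xi),
               tolerance = 1e-12)
})

test_that("choose_initial_point is deterministic, positive, and on the density surface", {
  ex <- gba_example()
  cond <- condition_slice(ex$conditions, 1)
  xi1 <- choose_initial_point(ex$model, cond, seed = 7)
  xi2 <- choose_initial_point(ex$model, cond, seed = 7)
  expect_identical(xi1, xi2)
  expect_true(all(xi1 > 0))
  MI <- ex$model$M[-1, ]
  expect_equal(sum(MI %*% xi1), cond$rho, tolerance = 1e-12 * cond$rho)

  # minimal model: the only importing column is the transport
  mm <- minimal_model(20, 1, 10, 1, 300, 10)
  xi0 <- choose_initial_point(mm$model, condition_slice(mm$conditions, 1))
  expect_equal(unname(xi0[1]), 300, tolerance = 1e-9)

  # structurally infeasible: no transport
  M <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
              dimnames = list(c("C1", "C2", "P"), c("e1", "r")))
  noimp <- gba_model(M, (M != 0) * 1, kcat_f = c(10, 10))
  expect_error(choose_initial_point(noimp, list(rho = 300, a = numeric(0))),
               "structurally infeasible")
})

test_that("solver reproduces the 1-D oracle on minimal models (spot checks)", {
  for (seed in c(2, 12)) {
    p <- random_params(seed)
    mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, p$a)
    or <- oracle_minimal(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, p$a)
    sol <- solve_condition(mm$model, condition_slice(mm$conditions, 1), fast_opts())
    expect_true(sol$converged)
    expect_equal(sol$mu, or$mu, tolerance = 1e-8)
    expect_equal(unname(sol$xi["r"]), or$xi_r, tolerance = 1e-4)
  }
})

test_that("solutions are deterministic given identical inputs and seed", {
  p <- random_params(8)
  mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, p$a)
  cond <- condition_slice(mm$conditions, 1)
  s1 <- solve_condition(mm$model, cond, fast_opts())
  s2 <- solve_condition(mm$model, cond, fast_opts())
  expect_identical(s1$mu, s2$mu)
  expect_identical(s1$xi, s2$xi)
})

test_that("converged solutions satisfy all balanced-growth invariants", {
  ex <- gba_example()
  res <- solve_all(ex$model, ex$conditions, fast_opts())
  for (sol in res$solutions) {
    expect_true(sol$converged)
    rho <- sum(sol$c)
    expect_equal(sum(sol$c), 300, tolerance = 1e-6 * 300)
    expect_gte(min(sol$c), -1e-9)
    expect_gte(min(sol$p), -1e-9)
    expect_equal(sum(sol$p), sol$c[["P"]], tolerance = 1e-6 * 300)
    expect_equal(sum(sol$phi), 1, tolerance = 1e-9)
    # dilution identity M_I v = mu c
    MI <- ex$model$M[-1, ]
    expect_lt(max(abs(MI %*% sol$v - sol$mu * sol$c)), 1e-6 * 300 * sol$mu)
  }
})

test_that("solve_all warm-starts and mu is nondecreasing in nutrient (oracle sweep)", {
  p <- random_params(31)
  a_sweep <- c(0.5, 2, 8, 32)
  mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, a_sweep)
  res <- solve_all(mm$model, mm$conditions, fast_opts())
  mus <- vapply(res$solutions, `[[`, numeric(1), "mu")
  expect_true(all(vapply(res$solutions, `[[`, logical(1), "converged")))
  expect_true(all(diff(mus) > -1e-9))
  for (k in seq_along(a_sweep)) {
    or <- oracle_minimal(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, a_sweep[k])
    expect_equal(mus[k], or$mu, tolerance = 1e-6)
  }
})

test_that("repeated identical conditions give identical growth rates", {
  p <- random_params(40)
  mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, rep(p$a, 3))
  res <- solve_all(mm$model, mm$conditions, fast_opts())
  mus <- vapply(res$solutions, `[[`, numeric(1), "mu")
  expect_lt(max(mus) - min(mus), 1e-9 * max(mus))
})

test_that("per-condition failures are contained, remaining conditions still run", {
  p <- random_params(50)
  # second condition has a = 0: vanishing transport rate, growth collapses
  mm <- minimal_model(p$kcat_t, p$K_t, p$kcat_r, p$K_r, p$rho, c(p$a, 0, p$a))
  res <- solve_all(mm$model, mm$conditions, fast_opts())
  expect_length(res$solutions, 3)
  expect_true(res$solutions[[1]]$converged)
  expect_true(res$solutions[[3]]$converged)
  # starved condition: mu near zero (or unconverged), but reported
  expect_s3_class(res$solutions[[2]], "gba_solution")
  expect_lt(abs(res$solutions[[2]]$mu), 0.05 * res$solutions[[1]]$mu)
})

test_that("reversible reactions are handled with direction feasibility", {
  # chain with a reversible middle enzyme still solves and keeps p >= 0
  ch <- chain3_model(40, 1, 30, 1, 15, 1, 300, 20)
  m <- ch$model
  m$kcat_b[["e1"]] <- 5
  m$K["C2", "e1"] <- 2           # product Km required for reversible form
  sol <- solve_condition(m, condition_slice(ch$conditions, 1), fast_opts())
  expect_true(sol$converged)
  expect_gte(min(sol$p), -1e-9)
  expect_gt(sol$mu, 0)
  # reversibility costs protein (backward flux erodes the net rate), so
  # growth cannot exceed the irreversible variant
  sol0 <- solve_condition(ch$model, condition_slice(ch$conditions, 1), fast_opts())
  expect_lte(sol$mu, sol0$mu * (1 + 1e-9))
})
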
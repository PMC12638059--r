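# The "Check Model" pipeline.

test_that("data integrity reports each offending cell with coordinates", {
  ex <- gba_example()
  expect_identical(check_data_integrity(ex$model, ex$conditions)$status, "pass")

  broken <- ex$model
  broken$K["C1", "e1"] <- NA
  res <- check_data_integrity(broken, ex$conditions)
  expect_identical(res$status, "fail")
  expect_match(res$messages, "K\\[C1, e1\\]", all = FALSE)

  # character input in conditions coerces to NA and is caught
  bad_cond <- gba_conditions(rho = c(300, "high"),
                             a = matrix(c(1, 10), 1, dimnames = list("x_S", NULL)))
  res2 <- check_data_integrity(ex$model, bad_cond)
  expect_identical(res2$status, "fail")
  expect_match(res2$messages, "rho", all = FALSE)
})

test_that("dimension check names the inconsistent matrix", {
  ex <- gba_example()
  expect_identical(check_dimensions(ex$model, ex$conditions)$status, "pass")

  short <- ex$model
  short$K <- short$K[, -5]
  res <- check_dimensions(short, ex$conditions)
  expect_identical(res$status, "fail")
  expect_match(res$messages, "^K is", all = FALSE)

  alien <- gba_conditions(rho = 300,
                          a = matrix(1, 1, dimnames = list("x_Glc", NULL)))
  res2 <- check_dimensions(ex$model, alien)
  expect_identical(res2$status, "fail")
  expect_match(res2$messages, "x_Glc", all = FALSE)
})

test_that("non-negativity: rho must be positive, a non-negative", {
  ex <- gba_example()
  expect_identical(check_nonnegativity(ex$model, ex$conditions)$status, "pass")

  zero_rho <- gba_conditions(rho = 0, a = matrix(1, 1, dimnames = list("x_S", NULL)))
  expect_identical(check_nonnegativity(ex$model, zero_rho)$status, "fail")

  neg_a <- gba_conditions(rho = 300, a = matrix(-1, 1, dimnames = list("x_S", NULL)))
  res <- check_nonnegativity(ex$model, neg_a)
  expect_identical(res$status, "fail")
  expect_match(res$messages, "x_S in condition cond1", all = FALSE)
})

test_that("mass conservation flags scaled and empty columns", {
  ex <- gba_example()
  expect_identical(check_mass_conservation(ex$model)$status, "pass")

  scaled <- ex$model
  scaled$M[, "e2"] <- scaled$M[, "e2"] * 2
  res <- check_mass_conservation(scaled)
  expect_identical(res$status, "fail")
  expect_match(res$messages, "column e2", all = FALSE)

  hollow <- ex$model
  hollow$M[, "e1"] <- 0
  expect_match(check_mass_conservation(hollow)$messages, "column e1", all = FALSE)
})

test_that("Km repair touches exactly the substrate cells that are zero", {
  ex <- gba_example()
  broken <- ex$model
  broken$K["C2", "e2"] <- 0          # substrate of e2
  out <- repair_km_defaults(broken)
  expect_identical(nrow(out$repairs), 1L)
  expect_identical(out$repairs$reactant, "C2")
  expect_identical(out$repairs$reaction, "e2")
  expect_equal(out$model$K["C2", "e2"], 0.1)
  # everything else untouched
  out$model$K["C2", "e2"] <- 0
  expect_identical(out$model$K, broken$K)

  # product of an irreversible reaction needs no Km: not repaired
  expect_equal(broken$K["C1", "t"], 0)
  expect_false(any(out$repairs$reaction == "t"))

  # clean model: identity, empty repair list
  clean <- repair_km_defaults(ex$model)
  expect_identical(nrow(clean$repairs), 0L)
  expect_identical(clean$model$K, ex$model$K)
})

test_that("reversible reactions also get product Km repair", {
  m <- single_reaction_model(reversible_kcat_b = 1)
  m$K["C", "t"] <- 0                 # product of the reversible transport
  out <- repair_km_defaults(m)
  expect_true(any(out$repairs$reactant == "C" & out$repairs$reaction == "t"))
  expect_equal(out$model$K["C", "t"], 0.1)
})

test_that("check_model aggregates, repairs, and enforces the size limit", {
  ex <- gba_example()
  report <- check_model(ex$model, ex$conditions)
  expect_s3_class(report, "gba_validation")
  expect_true(report$is_valid)
  expect_null(report$repaired_model)
  expect_identical(vapply(report$checks, `[[`, "", "name"),
                   c("data_integrity", "dimensions", "nonnegativity",
                     "mass_conservation", "km_repair", "size_limit"))

  # repaired model round: valid, with repaired_model attached
  broken <- ex$model
  broken$K["C1", "e1"] <- 0
  rep2 <- check_model(broken, ex$conditions)
  expect_true(rep2$is_valid)
  expect_false(is.null(rep2$repaired_model))
  expect_equal(rep2$repaired_model$K["C1", "e1"], 0.1)

  # size limit: 21 fails, 20 passes, --allow-large lifts it
  big <- generate_model(model_spec(n_rxn = 21, seed = 5, allow_large = TRUE))
  rep3 <- check_model(big$model, big$conditions)
  expect_false(rep3$is_valid)
  size <- rep3$checks[[which(vapply(rep3$checks, `[[`, "", "name") == "size_limit")]]
  expect_identical(size$status, "fail")
  expect_true(check_model(big$model, big$conditions, allow_large = TRUE)$is_valid)
  ok20 <- generate_model(model_spec(n_rxn = 20, seed = 5))
  expect_true(check_model(ok20$model, ok20$conditions)$is_valid)
})

test_that("check_model still reports later checks when dimensions fail", {
  ex <- gba_example()
  short <- ex$model
  short$K <- short$K[, -5]
  report <- check_model(short, ex$conditions)
  expect_false(report$is_valid)
  names_run <- vapply(report$checks, `[[`, "", "name")
  expect_true(all(c("data_integrity", "mass_conservation", "size_limit") %in% names_run))
})

test_that("validation is idempotent on the repaired model (property)", {
  for (seed in 1:20) {
    gm <- generate_model(model_spec(n_rxn = 6, seed = seed,
                                    reversible_fraction = 0.3))
    broken <- gm$model
    # zero out one substrate Km
    subs <- which(broken$M < 0, arr.ind = TRUE)
    pick <- subs[(seed %% nrow(subs)) + 1, ]
    broken$K[pick[1], pick[2]] <- 0
    r1 <- check_model(broken, gm$conditions)
    expect_true(r1$is_valid)
    expect_false(is.null(r1$repaired_model))
    r2 <- check_model(r1$repaired_model, gm$conditions)
    expect_true(r2$is_valid)
    expect_null(r2$repaired_model)
  }
})

test_that("generated models pass all checks with no repairs (property, 100 seeds)", {
  for (seed in 1:100) {
    gm <- generate_model(model_spec(
      n_ext = 1 + seed %% 3, n_rxn = 4 + seed %% 15, seed = seed,
      reversible_fraction = (seed %% 4) / 6,
      regulation_density = (seed %% 5) / 8, n_cond = 1 + seed %% 3))
    report <- check_model(gm$model, gm$conditions)
    expect_true(report$is_valid, label = sprintf("seed %d valid", seed))
    expect_null(report$repaired_model, label = sprintf("seed %d no repairs", seed))
  }
})
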
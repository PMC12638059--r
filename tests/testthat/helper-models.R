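# Model fixtures built in code.

# Three-reaction chain: transport t imports x_S as C1, enzyme e1 converts
# C1 -> C2, ribosome r polymerizes C2 -> P. Two free growth-scaled fluxes
# after the density constraint, the 2-D oracle case.
chain3_model <- function(kcat_t, K_t, kcat_e, K_e, kcat_r, K_r, rho, a) {
  M <- matrix(c(-1, 1, 0, 0,
                0, -1, 1, 0,
                0, 0, -1, 1), 4, 3,
              dimnames = list(c("x_S", "C1", "C2", "P"), c("t", "e1", "r")))
  K <- M * 0
  K["x_S", "t"] <- K_t
  K["C1", "e1"] <- K_e
  K["C2", "r"] <- K_r
  model <- gba_model(M, K, kcat_f = c(t = kcat_t, e1 = kcat_e, r = kcat_r))
  conditions <- gba_conditions(rho = rep(rho, length(a)),
                               a = matrix(a, 1, length(a),
                                          dimnames = list("x_S", NULL)))
  list(model = model, conditions = conditions)
}

# Single irreversible reaction x_S -> P plus ribosome? Smallest legal object
# for kinetics unit tests: one substrate, one product, free parameters.
single_reaction_model <- function(kcat = 2, Km = 1, reversible_kcat_b = 0,
                                  K_prod = 1, KA = 0, KI = 0) {
  M <- matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
              dimnames = list(c("x_S", "C", "P"), c("t", "r")))
  K <- M * 0
  K["x_S", "t"] <- Km
  K["C", "r"] <- 1
  if (reversible_kcat_b > 0) K["C", "t"] <- K_prod
  KA_m <- KI_m <- matrix(0, 2, 2, dimnames = list(c("C", "P"), c("t", "r")))
  if (KA > 0) KA_m["C", "t"] <- KA
  if (KI > 0) KI_m["C", "t"] <- KI
  gba_model(M, K, KA = KA_m, KI = KI_m,
            kcat_f = c(t = kcat, r = 10),
            kcat_b = c(t = reversible_kcat_b, r = 0))
}

random_params <- function(seed) {
  set.seed(seed)
  list(kcat_t = runif(1, 10, 80), K_t = runif(1, 0.5, 5),
       kcat_e = runif(1, 10, 80), K_e = runif(1, 0.5, 5),
       kcat_r = runif(1, 5, 40), K_r = runif(1, 0.5, 5),
       rho = runif(1, 200, 400), a = runif(1, 1, 50))
}

fast_opts <- function(...) gba_options(n_starts = 3, ...)
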
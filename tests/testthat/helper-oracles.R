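# Independent optimization oracles. These share no code with the package
# solver or kinetics: Michaelis-Menten turnover times are written out
# directly and the search is exhaustive grid + golden section.

golden_section_max <- function(f, lo, hi, tol = 1e-12, maxit = 200) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(maxit)) {
    if (hi - lo < tol * (abs(lo) + abs(hi))) break
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  x <- (lo + hi) / 2
  list(x = x, value = f(x))
}

# mu(xi_r) for the minimal 2-reaction self-replicator: the density
# constraint pins xi_t = rho, leaving a 1-D problem over xi_r in (0, rho).
oracle_minimal <- function(kcat_t, K_t, kcat_r, K_r, rho, a) {
  mu <- function(xr) {
    tau_t <- (1 / kcat_t) * (1 + K_t / a)
    cC <- rho - xr
    tau_r <- (1 / kcat_r) * (1 + K_r / pmax(cC, 1e-12))
    xr / (rho * tau_t + xr * tau_r)
  }
  xs <- seq(1e-9, rho - 1e-9, length.out = 1000)
  i <- which.max(mu(xs))
  ref <- golden_section_max(mu, xs[max(1, i - 1)], xs[min(1000, i + 1)])
  list(mu = ref$value, xi_r = ref$x, mu_fun = mu)
}

# mu(xi_e, xi_r) for the 3-reaction chain; nested grid refinement,
# 3 passes, 10x zoom per pass (100x total).
oracle_chain3 <- function(kcat_t, K_t, kcat_e, K_e, kcat_r, K_r, rho, a) {
  mu <- function(xe, xr) {
    c1 <- rho - xe
    c2 <- xe - xr
    tau_t <- (1 / kcat_t) * (1 + K_t / a)
    tau_e <- (1 / kcat_e) * (1 + K_e / pmax(c1, 1e-12))
    tau_r <- (1 / kcat_r) * (1 + K_r / pmax(c2, 1e-12))
    ifelse(c1 < 0 | c2 < 0, -1, xr / (rho * tau_t + xe * tau_e + xr * tau_r))
  }
  lo <- c(0, 0); hi <- c(rho, rho); best <- c(rho / 2, rho / 4)
  for (pass in 1:3) {
    xe <- seq(max(0, lo[1]), min(rho, hi[1]), length.out = 200)
    xr <- seq(max(0, lo[2]), min(rho, hi[2]), length.out = 200)
    G <- outer(xe, xr, mu)
    ij <- which(G == max(G), arr.ind = TRUE)[1, ]
    best <- c(xe[ij[1]], xr[ij[2]])
    span <- c(diff(range(xe)), diff(range(xr))) / 10
    lo <- best - span; hi <- best + span
  }
  list(mu = mu(best[1], best[2]), xi = best, mu_fun = mu)
}

# Random mass-conserving stoichiometry for the mass-fraction conversion
# property: draw weights and a signed S, then fix one product coefficient
# per column so that w %*% S = 0 exactly.
random_conservative_S <- function(seed) {
  set.seed(seed)
  n_r <- sample(3:6, 1)
  n_c <- sample(1:4, 1)
  w <- runif(n_r, 0.5, 50)
  S <- matrix(0, n_r, n_c)
  for (j in seq_len(n_c)) {
    k <- sample(2:n_r, 1)
    rows <- sample(n_r, k)
    subs <- rows[1:(k %/% 2)]
    prods <- rows[(k %/% 2 + 1):k]
    S[subs, j] <- -runif(length(subs), 0.5, 3)
    if (length(prods) > 1) S[prods[-1], j] <- runif(length(prods) - 1, 0.1, 1)
    # balance the first product so the column conserves mass exactly;
    # shrink the other products until the balancing coefficient is positive
    repeat {
      S[prods[1], j] <- 0
      bal <- -sum(w * S[, j]) / w[prods[1]]
      if (bal > 0) { S[prods[1], j] <- bal; break }
      S[prods[-1], j] <- S[prods[-1], j] * 0.05
    }
  }
  list(S = S, w = w)
}
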
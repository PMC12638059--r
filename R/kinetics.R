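# Convenience kinetics in mass units.
#
# For reaction alpha with substrates s (negative entries of column alpha of
# M) and products p (positive entries), the specific rate (flux per unit
# mass of catalyst protein, h^-1) is
#
#   k_alpha = reg * (kcat_f * prod_s(x_s/K_s) - kcat_b * prod_p(x_p/K_p)) /
#             (prod_s(1 + x_s/K_s) + prod_p(1 + x_p/K_p) - 1)
#
# with regulation prefactor reg = prod_act c/(KA + c) * prod_inh KI/(KI + c)
# over internal reactants only. For an irreversible reaction (kcat_b = 0)
# the product side drops out entirely, leaving
#
#   k_alpha = reg * kcat_f * prod_s(x_s/K_s) / prod_s(1 + x_s/K_s)
#
# whose reciprocal is the familiar turnover-time product form
# tau = (1/kcat_f) * prod_s(1 + K_s/x_s) * prod_act(1 + KA/c).
# A single substrate with no regulation recovers Michaelis-Menten exactly.
# Stoichiometric weights |M| != 1 contribute a single first-order saturation
# factor (no cooperativity exponents in mass units).

# Per-model precomputation of column supports; keyed off matrix contents so
# the solver can reuse it across thousands of evaluations.
kinetics_precompute <- function(model) {
  n_rxn <- n_reactions(model)
  int_rows <- internal_rows(model)
  cols <- vector("list", n_rxn)
  for (j in seq_len(n_rxn)) {
    m <- model$M[, j]
    sub <- which(m < 0)
    prod <- which(m > 0)
    act <- which(model$KA[, j] > 0)
    inh <- which(model$KI[, j] > 0)
    cols[[j]] <- list(
      sub = sub, prod = prod,
      K_sub = model$K[sub, j], K_prod = model$K[prod, j],
      act = act, KA = model$KA[act, j],
      inh = inh, KI = model$KI[inh, j],
      kf = model$kcat_f[[j]], kb = model$kcat_b[[j]])
  }
  list(cols = cols, n_ext = model$n_ext, int_rows = int_rows)
}

# Specific rates for all reactions at once; x = c(a, c) clamped.
rate_all <- function(kin, a, c_int, clamp = CONC_CLAMP) {
  x <- c(pmax(a, clamp), pmax(c_int, clamp))
  vapply(seq_along(kin$cols), function(j) {
    col <- kin$cols[[j]]
    rs <- x[col$sub] / col$K_sub
    sat_s <- prod(1 + rs)
    if (col$kb > 0) {
      rp <- x[col$prod] / col$K_prod
      num <- col$kf * prod(rs) - col$kb * prod(rp)
      den <- sat_s + prod(1 + rp) - 1
    } else {
      num <- col$kf * prod(rs)
      den <- sat_s
    }
    regulation_factor(col, x, kin$n_ext) * num / den
  }, numeric(1))
}

#' Specific reaction rate under convenience kinetics
#'
#' The specific rate of reaction `alpha` is the flux carried per unit mass of
#' its catalyzing protein (h^-1): saturable in each substrate, reversible
#' when `kcat_b > 0`, and scaled by multiplicative activation
#' (`c/(KA + c)`) and inhibition (`KI/(KI + c)`) prefactors from internal
#' reactants. Concentrations are clamped at a floor of `1e-12` g/L so the
#' evaluation is total; a negative value means the reversible reaction runs
#' net backward at this composition.
#'
#' @param model a validated [gba_model].
#' @param alpha reaction index or label.
#' @param a numeric vector of external concentrations (g/L), in the order of
#'   the `"x_"` rows of `M`.
#' @param c numeric vector of internal concentrations (g/L), in the order of
#'   the internal rows of `M`; the last entry is total protein.
#' @return Signed specific rate (h^-1).
#' @seealso [turnover_time()], [protein_demand()]
#' @export
#' @examples
#' ex <- gba_example()$model
#' # transport at half saturation runs at kcat/2
#' specific_rate(ex, "t", a = 5, c = rep(1, 5))
specific_rate <- function(model, alpha, a, c) {
  kin <- kinetics_precompute(model)
  j <- resolve_reaction(model, alpha)
  rate_one(kin, j, a, c)
}

rate_one <- function(kin, j, a, c_int, clamp = CONC_CLAMP) {
  x <- c(pmax(a, clamp), pmax(c_int, clamp))
  col <- kin$cols[[j]]
  rs <- x[col$sub] / col$K_sub
  sat_s <- prod(1 + rs)
  if (col$kb > 0) {
    rp <- x[col$prod] / col$K_prod
    num <- col$kf * prod(rs) - col$kb * prod(rp)
    den <- sat_s + prod(1 + rp) - 1
  } else {
    num <- col$kf * prod(rs)
    den <- sat_s
  }
  reg <- regulation_factor(col, x, kin$n_ext)
  reg * num / den
}

regulation_factor <- function(col, x, n_ext) {
  reg <- 1
  if (length(col$act)) {
    ca <- x[n_ext + col$act]
    reg <- reg * prod(ca / (col$KA + ca))
  }
  if (length(col$inh)) {
    ci <- x[n_ext + col$inh]
    reg <- reg * prod(col$KI / (col$KI + ci))
  }
  reg
}

resolve_reaction <- function(model, alpha) {
  if (is.character(alpha)) {
    j <- match(alpha, colnames(model$M))
    if (is.na(j)) stop(sprintf("unknown reaction: %s", alpha), call. = FALSE)
    return(j)
  }
  as.integer(alpha)
}

#' Turnover time of a reaction
#'
#' The turnover time `tau_alpha` is the mass of catalyst protein needed per
#' unit flux: the reciprocal of [specific_rate()]. For an irreversible
#' reaction with activators it takes the product form
#' `(1/kcat_f) * prod_s(1 + K/x_s) * prod_act(1 + KA/c)`. It is `Inf` at
#' zero rate and negative for a reversible reaction running net backward.
#'
#' @inheritParams specific_rate
#' @return Turnover time (h); may be infinite or negative.
#' @export
turnover_time <- function(model, alpha, a, c) {
  1 / specific_rate(model, alpha, a, c)
}

#' Protein demand of a flux
#'
#' Under balanced growth the protein concentration catalyzing reaction
#' `alpha` must equal `p_alpha = v_alpha * tau_alpha(a, c)`. A negative
#' demand (flux against the net thermodynamic direction of a reversible
#' reaction) is infeasible and is rejected by the solver.
#'
#' @inheritParams specific_rate
#' @param v_alpha flux through the reaction (g/L/h).
#' @return Protein concentration `p_alpha` (g/L).
#' @export
protein_demand <- function(model, alpha, v_alpha, a, c) {
  tau <- turnover_time(model, alpha, a, c)
  if (v_alpha == 0 && is.finite(tau)) return(0)
  v_alpha * tau
}
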
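# Random valid GBA models, the minimal closed-form self-replicator used as
# an optimization oracle, and parameter-lumping helpers for coarse-graining.

#' Specification for a random GBA model
#'
#' Defaults describe a biologically plausible coarse-grained model in mass
#' units: turnover numbers of 1-100 per hour, Michaelis constants of
#' 0.1-10 g/L, and cell densities of 200-400 g/L (the cytoplasmic dry-mass
#' density range of typical bacteria).
#'
#' @param n_ext number of external reactants (each gets its own transport
#'   column).
#' @param n_rxn total number of reactions including transports and the
#'   ribosome; `n_rxn >= n_ext + 1`.
#' @param n_int optional number of internal reactants (metabolites + P);
#'   derived from the chain topology when `NULL` and validated against it
#'   otherwise.
#' @param reversible_fraction fraction of enzymatic reactions made
#'   reversible.
#' @param regulation_density probability that an enzymatic reaction receives
#'   one activator and/or one inhibitor.
#' @param n_cond number of growth conditions to generate.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param kcat_range,km_range,rho_range,a_range parameter ranges (h^-1 and
#'   g/L).
#' @param allow_large permit `n_rxn > 20` (for exercising the validator's
#'   size limit).
#' @return A list of class `gba_model_spec`.
#' @export
model_spec <- function(n_ext = 1, n_rxn = 5, n_int = NULL,
                       reversible_fraction = 0, regulation_density = 0,
                       n_cond = 1, seed = 1,
                       kcat_range = c(1, 100), km_range = c(0.1, 10),
                       rho_range = c(200, 400), a_range = c(1, 50),
                       allow_large = FALSE) {
  n_ext <- as.integer(n_ext); n_rxn <- as.integer(n_rxn)
  if (n_rxn < 2) stop("n_rxn must be at least 2", call. = FALSE)
  if (n_ext < 1) stop("n_ext must be at least 1", call. = FALSE)
  if (n_rxn < n_ext + 1)
    stop("unsatisfiable spec: need one transport per external reactant plus the ribosome", call. = FALSE)
  if (n_rxn > MAX_REACTIONS && !allow_large)
    stop(sprintf("n_rxn exceeds the %d-reaction solver limit; set allow_large = TRUE to generate anyway",
                 MAX_REACTIONS), call. = FALSE)
  n_enz <- n_rxn - n_ext - 1L
  derived_int <- n_enz + 2L            # chain metabolites + P
  if (is.null(n_int)) n_int <- derived_int
  if (n_int != derived_int)
    stop(sprintf("unsatisfiable spec: chain topology with %d enzymatic reactions needs n_int = %d",
                 n_enz, derived_int), call. = FALSE)
  if (n_int < 2) stop("unsatisfiable spec: n_int < 2", call. = FALSE)
  structure(list(n_ext = n_ext, n_int = as.integer(n_int), n_rxn = n_rxn,
                 n_enz = n_enz, reversible_fraction = reversible_fraction,
                 regulation_density = regulation_density,
                 n_cond = as.integer(n_cond), seed = as.integer(seed),
                 kcat_range = kcat_range, km_range = km_range,
                 rho_range = rho_range, a_range = a_range),
            class = "gba_model_spec")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a random valid GBA model
#'
#' Topology: every external reactant is imported by its own transport column
#' into the first chain metabolite; enzymatic reactions form a connected
#' conversion chain `C1 -> C2 -> ...`; the ribosome consumes the last chain
#' metabolite and produces total protein `P` with mass fraction 1. Column
#' supports are drawn first and magnitudes normalized to the +/-1 sum rule,
#' so mass conservation holds by construction, never by rejection. Output
#' always passes [check_model()] with no repairs, deterministically for a
#' given seed.
#'
#' @param spec a [model_spec()].
#' @return A list with `model` and `conditions`.
#' @export
#' @examples
#' gm <- generate_model(model_spec(n_rxn = 5, seed = 7))
#' check_model(gm$model, gm$conditions)$is_valid
generate_model <- function(spec) {
  stopifnot(inherits(spec, "gba_model_spec"))
  with_seed(spec$seed, generate_model_impl(spec))
}

generate_model_impl <- function(spec) {
  n_met <- spec$n_int - 1L             # chain metabolites, P excluded
  ext <- paste0("x_", if (spec$n_ext == 1) "S" else paste0("S", seq_len(spec$n_ext)))
  mets <- paste0("C", seq_len(n_met))
  reactants <- c(ext, mets, PROTEIN_LABEL)
  reactions <- c(paste0("t", seq_len(spec$n_ext)),
                 if (spec$n_enz > 0) paste0("e", seq_len(spec$n_enz)),
                 RIBOSOME_LABEL)
  n_rxn <- spec$n_rxn
  M <- matrix(0, length(reactants), n_rxn,
              dimnames = list(reactants, reactions))

  # transports: import external j; product mass split between C1 and at most
  # one other chain metabolite
  for (j in seq_len(spec$n_ext)) {
    M[ext[j], j] <- -1
    if (n_met > 1 && stats::runif(1) < 0.3) {
      other <- sample(2:n_met, 1)
      w <- stats::runif(1, 0.5, 0.95)
      M[mets[1], j] <- w
      M[mets[other], j] <- 1 - w
    } else {
      M[mets[1], j] <- 1
    }
  }
  # enzymatic chain: e_k converts C_k (possibly plus an earlier metabolite)
  # into C_{k+1}
  for (k in seq_len(spec$n_enz)) {
    jcol <- spec$n_ext + k
    if (k > 1 && stats::runif(1) < 0.3) {
      extra <- sample(seq_len(k - 1), 1)
      w <- stats::runif(1, 0.6, 0.95)
      M[mets[k], jcol] <- -w
      M[mets[extra], jcol] <- -(1 - w)
    } else {
      M[mets[k], jcol] <- -1
    }
    M[mets[k + 1], jcol] <- 1
  }
  # ribosome: consumes the last chain metabolite (plus at most one other),
  # produces P with mass fraction 1
  if (n_met > 1 && stats::runif(1) < 0.3) {
    extra <- sample(seq_len(n_met - 1), 1)
    w <- stats::runif(1, 0.6, 0.95)
    M[mets[n_met], n_rxn] <- -w
    M[mets[extra], n_rxn] <- -(1 - w)
  } else {
    M[mets[n_met], n_rxn] <- -1
  }
  M[PROTEIN_LABEL, n_rxn] <- 1

  # kinetic parameters: positive Km for every participating reactant
  K <- M * 0
  K[M != 0] <- runif_range(sum(M != 0), spec$km_range)
  kcat_f <- runif_range(n_rxn, spec$kcat_range)
  kcat_b <- numeric(n_rxn)
  if (spec$reversible_fraction > 0 && spec$n_enz > 0) {
    enz_cols <- spec$n_ext + seq_len(spec$n_enz)
    rev <- enz_cols[stats::runif(spec$n_enz) < spec$reversible_fraction]
    kcat_b[rev] <- kcat_f[rev] * stats::runif(length(rev), 0.05, 0.5)
  }

  KA <- KI <- matrix(0, spec$n_int, n_rxn,
                     dimnames = list(c(mets, PROTEIN_LABEL), reactions))
  if (spec$regulation_density > 0 && spec$n_enz > 0) {
    for (k in seq_len(spec$n_enz)) {
      jcol <- spec$n_ext + k
      if (stats::runif(1) < spec$regulation_density)
        KA[sample(n_met, 1), jcol] <- runif_range(1, spec$km_range)
      if (stats::runif(1) < spec$regulation_density)
        KI[sample(n_met, 1), jcol] <- runif_range(1, spec$km_range)
    }
  }

  model <- gba_model(M, K, KA = KA, KI = KI, kcat_f = kcat_f, kcat_b = kcat_b)
  conditions <- gba_conditions(
    rho = runif_range(spec$n_cond, spec$rho_range),
    a = matrix(runif_range(spec$n_ext * spec$n_cond, spec$a_range),
               spec$n_ext, spec$n_cond, dimnames = list(ext, NULL)))
  list(model = model, conditions = conditions)
}

#' Minimal two-reaction self-replicator
#'
#' The smallest GBA model: a transporter `t` imports the external substrate
#' `x_S` as metabolite `C`, and the ribosome `r` polymerizes `C` into total
#' protein `P`, both with Michaelis-Menten kinetics. The density constraint
#' forces `xi_t = rho`, which reduces the growth program to a 1-D search
#' over `xi_r` -- the package's closed-form optimization oracle case.
#'
#' @param kcat_t,kcat_r turnover numbers (h^-1), positive.
#' @param K_t,K_r Michaelis constants (g/L), positive.
#' @param rho cell density (g/L).
#' @param a external substrate concentration(s) (g/L); a vector gives one
#'   condition per entry.
#' @return A list with `model` and `conditions`.
#' @export
#' @examples
#' mm <- minimal_model(20, 1, 10, 1, rho = 300, a = c(1, 10, 100))
minimal_model <- function(kcat_t, K_t, kcat_r, K_r, rho, a) {
  stopifnot(kcat_t > 0, K_t > 0, kcat_r > 0, K_r > 0, rho > 0, all(a >= 0))
  M <- matrix(c(-1, 1, 0,
                0, -1, 1), 3, 2,
              dimnames = list(c("x_S", "C", "P"), c("t", "r")))
  K <- M * 0
  K["x_S", "t"] <- K_t
  K["C", "r"] <- K_r
  model <- gba_model(M, K, kcat_f = c(t = kcat_t, r = kcat_r))
  conditions <- gba_conditions(
    rho = rep(rho, length(a)),
    a = matrix(a, 1, length(a), dimnames = list("x_S", NULL)))
  list(model = model, conditions = conditions)
}

#' Lump turnover numbers of merged reactions
#'
#' Coarse-graining merges several elementary reactions into one idealized
#' reaction. The rule of thumb for its effective turnover number is the
#' arithmetic mean of the member kcats for reactions in parallel, and the
#' harmonic mean for reactions in series (the slowest step dominates).
#'
#' @param kcats positive numeric vector of member turnover numbers (h^-1).
#' @param mode `"parallel"` or `"series"`.
#' @return Effective turnover number (h^-1).
#' @export
#' @examples
#' lump_kcat(c(1, 3), "parallel")  # 2
#' lump_kcat(c(1, 3), "series")    # 1.5
lump_kcat <- function(kcats, mode = c("parallel", "series")) {
  mode <- match.arg(mode)
  kcats <- as.numeric(kcats)
  if (length(kcats) == 0 || any(!is.finite(kcats)) || any(kcats <= 0))
    stop("kcats must be a nonempty vector of positive values", call. = FALSE)
  if (mode == "parallel") mean(kcats) else length(kcats) / sum(1 / kcats)
}

#' Lump Michaelis constants of merged substrates
#'
#' For an idealized lumped reaction, a reasonable effective Michaelis
#' constant is half the summed concentration of the substrates involved,
#' reflecting typical enzyme saturation around its operating point. A zero
#' result (all substrates absent) is later repaired to the 0.1 g/L default
#' by [repair_km_defaults()] if used as a substrate Km.
#'
#' @param substrate_concentrations non-negative numeric vector (g/L).
#' @return Effective Km (g/L): `sum(x) / 2`.
#' @export
#' @examples
#' lump_km(c(1, 2, 3))  # 3
lump_km <- function(substrate_concentrations) {
  x <- as.numeric(substrate_concentrations)
  if (length(x) == 0)
    stop("substrate_concentrations must be nonempty", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("substrate_concentrations must be non-negative", call. = FALSE)
  sum(x) / 2
}
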
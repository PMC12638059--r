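#' gbasolve: growth balance analysis for coarse-grained cell models
#'
#' Growth balance analysis (GBA) predicts the optimal growth rate and the full
#' biomass composition (metabolites and proteins) of a self-replicating cell
#' from three ingredients: a mass-fraction stoichiometric matrix, saturable
#' kinetic rate laws, and a fixed total cell density. The package covers the
#' whole desk-scale workflow: model construction and spreadsheet interchange
#' ([gba_model()], [read_gba()], [write_gba()]), validation with automatic
#' Michaelis-constant repair ([check_model()]), convenience-kinetics evaluation
#' ([specific_rate()], [turnover_time()]), constrained growth-rate optimization
#' ([solve_condition()], [solve_all()]), reporting ([write_results()],
#' [plot_sweep()], [export_flux_map()]), and synthetic model generation
#' ([generate_model()], [minimal_model()]).
#'
#' @keywords internal
"_PACKAGE"

# Shared label conventions:
#  * external reactants carry the "x_" prefix and occupy the leading rows of M;
#  * the last internal row is total protein "P";
#  * reaction columns are ordered transport, enzymatic, ribosome; the last
#    column is the ribosome reaction "r" producing P.

EXT_PREFIX <- "x_"
PROTEIN_LABEL <- "P"
RIBOSOME_LABEL <- "r"
MAX_REACTIONS <- 20L
KM_DEFAULT <- 0.1        # g/L, repair value for zero substrate Michaelis constants
CONC_CLAMP <- 1e-12      # g/L, evaluation floor inside kinetics

#' Construct a GBA model
#'
#' A GBA model is defined by five parameter matrices sharing row/column
#' ordering: the mass-fraction matrix `M` (dimensionless; each column's
#' positive entries sum to 1 and negative entries to -1, so every reaction
#' conserves mass), the Michaelis-constant matrix `K` (g/L), the activation
#' and inhibition matrices `KA`/`KI` (g/L, internal reactants only, 0 = no
#' effect), and forward/backward turnover numbers `kcat_f`/`kcat_b` (h^-1,
#' mass of product per mass of catalyst protein per hour; `kcat_b = 0` marks
#' an irreversible reaction).
#'
#' Row labels of `M`/`K` name reactants: external reactants first, prefixed
#' `"x_"`, then internal reactants with total protein `"P"` last. Column
#' labels name reactions, ordered transport, enzymatic, ribosome, with the
#' ribosome reaction `"r"` last.
#'
#' @param M numeric matrix of mass fractions, reactants x reactions, with
#'   complete dimnames.
#' @param K numeric matrix of Michaelis constants (g/L), same shape as `M`.
#' @param KA,KI numeric matrices of activation/inhibition constants (g/L) over
#'   internal reactant rows only; `NULL` means no regulation. Full-height
#'   matrices are accepted when their external rows are all zero (dropped with
#'   a warning).
#' @param kcat_f numeric vector of forward turnover numbers (h^-1), one per
#'   reaction.
#' @param kcat_b numeric vector of backward turnover numbers (h^-1);
#'   `NULL` means all reactions irreversible.
#' @param check logical; verify structural conventions (label ordering and
#'   shapes). Numeric invariants are the job of [check_model()].
#'
#' @return An object of class `gba_model`: a list with elements `M`, `K`,
#'   `KA`, `KI`, `kcat_f`, `kcat_b`, `n_ext`.
#' @seealso [check_model()], [gba_conditions()], [gba_example()]
#' @export
#' @examples
#' ex <- gba_example()
#' ex$model
gba_model <- function(M, K, KA = NULL, KI = NULL, kcat_f, kcat_b = NULL,
                      check = TRUE) {
  M <- as_labelled_matrix(M, "M")
  K <- as_labelled_matrix(K, "K")
  n_rxn <- ncol(M)
  reactants <- rownames(M)
  is_ext <- startsWith(reactants, EXT_PREFIX)
  n_ext <- sum(is_ext)
  int_labels <- reactants[!is_ext]

  zero_int <- matrix(0, length(int_labels), n_rxn,
                     dimnames = list(int_labels, colnames(M)))
  KA <- normalize_regulation(KA, zero_int, "KA")
  KI <- normalize_regulation(KI, zero_int, "KI")

  kcat_f <- as.numeric(kcat_f)
  if (is.null(kcat_b)) kcat_b <- numeric(n_rxn)
  kcat_b <- as.numeric(kcat_b)
  names(kcat_f) <- names(kcat_b) <- colnames(M)

  model <- structure(
    list(M = M, K = K, KA = KA, KI = KI,
         kcat_f = kcat_f, kcat_b = kcat_b, n_ext = n_ext),
    class = "gba_model")

  if (check) assert_model_structure(model)
  model
}

as_labelled_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(sprintf("matrix %s must have row and column labels", what), call. = FALSE)
  x
}

normalize_regulation <- function(X, zero_int, what) {
  if (is.null(X)) return(zero_int)
  X <- as_labelled_matrix(X, what)
  ext <- startsWith(rownames(X), EXT_PREFIX)
  if (any(ext)) {
    if (any(X[ext, , drop = FALSE] != 0, na.rm = TRUE))
      stop(sprintf("%s defines regulation on external reactants; only internal reactants may regulate", what),
           call. = FALSE)
    warning(sprintf("dropping all-zero external rows from %s", what), call. = FALSE)
    X <- X[!ext, , drop = FALSE]
  }
  X
}

assert_model_structure <- function(model) {
  M <- model$M
  reactants <- rownames(M)
  is_ext <- startsWith(reactants, EXT_PREFIX)
  if (model$n_ext > 0 && any(which(is_ext) != seq_len(model$n_ext)))
    stop("external reactants (\"x_\" prefix) must occupy the leading rows of M", call. = FALSE)
  if (utils::tail(reactants, 1) != PROTEIN_LABEL)
    stop("last internal reactant row must be labeled \"P\" (total protein)", call. = FALSE)
  if (utils::tail(colnames(M), 1) != RIBOSOME_LABEL)
    stop("last reaction column must be labeled \"r\" (ribosome)", call. = FALSE)
  if (!identical(dim(model$K), dim(M)))
    stop("K must have the same shape as M", call. = FALSE)
  if (!identical(rownames(model$KA), internal_labels(model)) ||
      !identical(rownames(model$KI), internal_labels(model)))
    stop("KA and KI must cover exactly the internal reactant rows", call. = FALSE)
  if (length(model$kcat_f) != ncol(M) || length(model$kcat_b) != ncol(M))
    stop("kcat_f and kcat_b must have one entry per reaction", call. = FALSE)
  invisible(model)
}

n_reactions <- function(model) ncol(model$M)
n_reactants <- function(model) nrow(model$M)
n_internal <- function(model) nrow(model$M) - model$n_ext
external_labels <- function(model) rownames(model$M)[seq_len(model$n_ext)]
internal_labels <- function(model) rownames(model$M)[internal_rows(model)]
internal_rows <- function(model) model$n_ext + seq_len(n_internal(model))

# Internal block of M: rows of internal reactants, used throughout the solver
# since balanced growth gives c = M_I %*% xi.
M_internal <- function(model) model$M[internal_rows(model), , drop = FALSE]

#' @export
print.gba_model <- function(x, ...) {
  cat(sprintf("GBA model: %d reactions (%d transport-candidate + ribosome \"r\"), %d reactants (%d external, %d internal)\n",
              n_reactions(x), n_reactions(x) - 1L, n_reactants(x), x$n_ext,
              n_internal(x)))
  rev <- sum(x$kcat_b > 0)
  reg <- sum(x$KA > 0) + sum(x$KI > 0)
  cat(sprintf("  reversible reactions: %d; regulatory interactions: %d\n", rev, reg))
  cat("  reactions:", paste(colnames(x$M), collapse = ", "), "\n")
  cat("  reactants:", paste(rownames(x$M), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a set of growth conditions
#'
#' Each growth condition fixes the cell density `rho` (g/L) and the external
#' reactant concentrations `a` (g/L). Rows of `a` must match the `"x_"`
#' reactant rows of the model's mass-fraction matrix, in order.
#'
#' @param rho numeric vector of cell densities, one per condition (g/L).
#' @param a numeric matrix of external concentrations, `n_ext` rows x one
#'   column per condition (g/L); may be `NULL` when the model has no external
#'   reactants. A vector is taken as a single external reactant across
#'   conditions.
#' @param labels optional condition labels; defaults to `cond1, cond2, ...`.
#'
#' @return An object of class `gba_conditions` with elements `rho` (named
#'   vector) and `a` (matrix).
#' @export
#' @examples
#' gba_conditions(rho = c(300, 300), a = matrix(c(1, 10), 1,
#'   dimnames = list("x_S", NULL)))
gba_conditions <- function(rho, a = NULL, labels = NULL) {
  rho <- suppressWarnings(as.numeric(rho))
  n_cond <- length(rho)
  if (n_cond < 1) stop("at least one condition is required", call. = FALSE)
  if (is.null(a)) {
    a <- matrix(numeric(0), 0, n_cond)
  } else {
    if (is.null(dim(a))) a <- matrix(a, nrow = 1)
    a <- as.matrix(a)
    suppressWarnings(storage.mode(a) <- "double")
    if (ncol(a) != n_cond)
      stop("a must have one column per condition", call. = FALSE)
  }
  if (is.null(labels)) labels <- colnames(a)
  if (is.null(labels)) labels <- paste0("cond", seq_len(n_cond))
  names(rho) <- labels
  colnames(a) <- labels
  structure(list(rho = rho, a = a), class = "gba_conditions")
}

n_conditions <- function(conditions) length(conditions$rho)
condition_labels <- function(conditions) names(conditions$rho)

#' Extract a single growth condition
#'
#' Returns condition `k` as the plain `list(rho =, a =, label =)` structure
#' that [growth_rate()] and [solve_condition()] operate on.
#'
#' @param conditions a [gba_conditions].
#' @param k condition index.
#' @return A list with `rho` (g/L), `a` (named numeric, g/L), `label`.
#' @export
condition_slice <- function(conditions, k) {
  list(rho = unname(conditions$rho[[k]]),
       a = stats::setNames(conditions$a[, k], rownames(conditions$a)),
       label = condition_labels(conditions)[[k]])
}

#' @export
print.gba_conditions <- function(x, ...) {
  cat(sprintf("GBA conditions: %d condition(s), %d external reactant(s)\n",
              n_conditions(x), nrow(x$a)))
  tab <- rbind(rho = x$rho, x$a)
  print(tab)
  invisible(x)
}

#' Convert a mol-based stoichiometric matrix to mass fractions
#'
#' The mass-fraction matrix M used by GBA is the ordinary stoichiometric
#' matrix S with each row scaled by the molecular weight of its reactant and
#' each column normalized so the produced mass sums to 1 (consumed mass then
#' sums to -1). Mass conservation requires `w %*% S = 0` for every column; a
#' violated column is an error because no normalization can repair it.
#'
#' @param S numeric matrix of signed stoichiometric coefficients (mol based),
#'   reactants x reactions.
#' @param w numeric vector of molecular weights (g/mol), one per reactant,
#'   all positive.
#' @param tol absolute tolerance on the mass-conservation residual
#'   `w %*% S` per column, relative to the column's positive mass.
#'
#' @return The mass-fraction matrix, same shape and dimnames as `S`.
#' @export
#' @examples
#' S <- matrix(c(-1, -1, 2), 3, 1, dimnames = list(c("A", "B", "C"), "v1"))
#' mass_fraction_matrix(S, w = c(2, 3, 2.5))  # column (-0.4, -0.6, 1)
mass_fraction_matrix <- function(S, w, tol = 1e-9) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  w <- as.numeric(w)
  if (length(w) != nrow(S)) stop("w must have one weight per reactant row", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0)) stop("molecular weights must be positive", call. = FALSE)
  G <- S * w                        # mass flows, g per unit reaction extent
  M <- S * 0
  for (j in seq_len(ncol(S))) {
    g <- G[, j]
    pos <- sum(g[g > 0])
    if (pos == 0)
      stop(sprintf("column %s of S is all zero (or has no products)", column_name(S, j)), call. = FALSE)
    if (abs(sum(g)) > tol * pos)
      stop(sprintf("column %s violates mass conservation: w %%*%% S = %.3g (must be 0)",
                   column_name(S, j), sum(g)), call. = FALSE)
    M[, j] <- g / pos
  }
  M
}

column_name <- function(X, j) {
  if (!is.null(colnames(X))) colnames(X)[j] else as.character(j)
}

#' Packaged five-reaction example model
#'
#' A minimal but complete GBA model in the classic coarse-grained style: one
#' transport reaction imports an external substrate, a linear chain of three
#' enzymatic reactions converts it to a precursor, and the ribosome reaction
#' `"r"` polymerizes the precursor into total protein `"P"`. All reactions
#' are irreversible with no activation or inhibition, so every rate law
#' reduces to single-substrate Michaelis-Menten kinetics. Parameter values
#' are plausible fixtures (kcat of tens per hour, Km of a few g/L, density
#' 300 g/L), chosen for a well-conditioned optimum, not fitted to data.
#'
#' @return A list with elements `model` ([gba_model]) and `conditions`
#'   ([gba_conditions]; four conditions sweeping the external substrate over
#'   0.1 to 100 g/L).
#' @export
#' @examples
#' ex <- gba_example()
#' colSums(pmax(ex$model$M, 0))   # every reaction produces unit mass
gba_example <- function() {
  reactants <- c("x_S", "C1", "C2", "C3", "C4", "P")
  reactions <- c("t", "e1", "e2", "e3", "r")
  M <- matrix(0, 6, 5, dimnames = list(reactants, reactions))
  chain <- c("x_S", "C1", "C2", "C3", "C4", "P")
  for (j in 1:5) {
    M[chain[j], j] <- -1
    M[chain[j + 1], j] <- 1
  }
  K <- M * 0
  K["x_S", "t"] <- 5
  K["C1", "e1"] <- 1
  K["C2", "e2"] <- 2
  K["C3", "e3"] <- 1
  K["C4", "r"] <- 5
  kcat_f <- c(t = 80, e1 = 60, e2 = 40, e3 = 50, r = 20)
  model <- gba_model(M, K, kcat_f = kcat_f)
  conditions <- gba_conditions(
    rho = rep(300, 4),
    a = matrix(c(0.1, 1, 10, 100), 1, dimnames = list("x_S", NULL)))
  list(model = model, conditions = conditions)
}

# Structurally valid chain skeleton used by write_template(): one external
# substrate, a transport column, an enzymatic chain, and the ribosome.
template_model <- function(n_reactants, n_reactions) {
  n_reactants <- as.integer(n_reactants)
  n_reactions <- as.integer(n_reactions)
  if (is.na(n_reactants) || n_reactants < 2)
    stop("n_reactants must be at least 2 (one substrate plus protein \"P\")", call. = FALSE)
  if (is.na(n_reactions) || n_reactions < 2)
    stop("n_reactions must be at least 2 (one transport plus the ribosome \"r\")", call. = FALSE)
  reactants <- c("x_S",
                 if (n_reactants > 2) paste0("C", seq_len(n_reactants - 2)),
                 PROTEIN_LABEL)
  reactions <- c("t",
                 if (n_reactions > 2) paste0("e", seq_len(n_reactions - 2)),
                 RIBOSOME_LABEL)
  M <- matrix(0, n_reactants, n_reactions, dimnames = list(reactants, reactions))
  # cycle a unit-mass chain through the non-protein reactants; the ribosome
  # column always consumes the last metabolite and produces P
  n_chain <- n_reactants - 1L
  for (j in seq_len(n_reactions - 1L)) {
    idx <- (j - 1L) %% n_chain + 1L
    to <- if (n_chain == 1L) PROTEIN_LABEL else reactants[idx %% n_chain + 1L]
    M[reactants[idx], j] <- -1
    M[to, j] <- 1
  }
  M[reactants[n_chain], n_reactions] <- -1
  M[PROTEIN_LABEL, n_reactions] <- 1
  K <- (M != 0) * 1
  kcat_f <- rep(10, n_reactions)
  model <- gba_model(M, K, kcat_f = kcat_f)
  conditions <- gba_conditions(rho = 300,
                               a = matrix(10, 1, 1, dimnames = list("x_S", NULL)))
  list(model = model, conditions = conditions)
}
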
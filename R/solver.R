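# Balanced-growth optimization.
#
# Change of variables: xi_alpha = v_alpha / mu (growth-scaled flux, g/L).
# Under balanced growth every internal concentration obeys M v = mu c, so
# c = M_I xi with M_I the internal rows of M, and the density constraint
# sum(c) = rho becomes LINEAR in xi. Protein closure fixes the growth rate:
# total protein c_P must equal sum_alpha p_alpha = mu * sum_alpha xi_alpha *
# tau_alpha, hence
#
#   mu(xi) = c_P / sum_alpha xi_alpha * tau_alpha(a, c).
#
# The program solved per condition is
#   maximize mu(xi)
#   s.t.  sum(M_I xi) = rho          (density, linear)
#         (M_I xi)_i >= 0            (concentrations)
#         xi_alpha * tau_alpha >= 0  (reversible reactions must carry flux
#                                     along their net thermodynamic direction)
#         xi_alpha >= 0              (irreversible reactions)
#
# solved by an augmented-Lagrangian outer loop (Rockafellar multiplier
# updates for the inequalities) around stats::optim inner minimizations,
# with multistart and warm starting. Decision variables are scaled to
# u = xi / rho so the problem is O(1) regardless of density.

#' Solver options
#'
#' @param solver inner minimizer of the augmented Lagrangian:
#'   `"lbfgs"` (default; `stats::optim` L-BFGS-B, bound-constrained),
#'   `"bfgs"`, or `"neldermead"` (bounds folded into the augmented
#'   Lagrangian for the latter two).
#' @param n_starts number of multistart initial points (the warm start, when
#'   given, is added on top).
#' @param seed base seed for the deterministic initial points.
#' @param tol_obj relative objective tolerance between outer iterations.
#' @param tol_constraint feasibility tolerance on the scaled constraints
#'   (density residual is `tol_constraint * rho` in g/L).
#' @param maxit total inner-iteration budget per start.
#' @param grad_step relative step for the central-difference gradient.
#' @param progress `TRUE`, `FALSE`, or a `function(label, k, n, mu)` called
#'   after each condition.
#' @return A list of class `gba_options`.
#' @export
gba_options <- function(solver = c("lbfgs", "bfgs", "neldermead"),
                        n_starts = 10, seed = 42,
                        tol_obj = 1e-9, tol_constraint = 1e-8,
                        maxit = 2000, grad_step = 1e-7,
                        progress = FALSE) {
  structure(list(solver = match.arg(solver), n_starts = as.integer(n_starts),
                 seed = as.integer(seed), tol_obj = tol_obj,
                 tol_constraint = tol_constraint, maxit = as.integer(maxit),
                 grad_step = grad_step, progress = progress),
            class = "gba_options")
}

as_condition <- function(condition, model = NULL) {
  if (inherits(condition, "gba_conditions")) {
    if (n_conditions(condition) != 1)
      stop("pass a single condition (use condition_slice via solve_all for sweeps)", call. = FALSE)
    return(condition_slice(condition, 1))
  }
  stopifnot(is.list(condition), !is.null(condition$rho))
  if (is.null(condition$a)) condition$a <- numeric(0)
  if (is.null(condition$label)) condition$label <- "cond1"
  condition
}

#' Balanced growth rate at a given growth-scaled flux vector
#'
#' Evaluates `mu(xi) = c_P / sum(xi * tau)` with `c = M_I xi`: the unique
#' growth rate at which the protein produced by the ribosome exactly covers
#' the protein demand `p = v * tau` of all reactions, given fluxes
#' `v = mu * xi`. Returns `NA` when the composition is infeasible
#' (`sum(xi * tau) <= 0`).
#'
#' @param model a validated [gba_model].
#' @param condition a single growth condition: list with `rho` (g/L) and `a`
#'   (external concentrations, g/L), or a one-column [gba_conditions].
#' @param xi numeric vector of growth-scaled fluxes `v/mu` (g/L), one per
#'   reaction.
#' @return Growth rate (h^-1), or `NA_real_` if infeasible.
#' @export
#' @examples
#' mm <- minimal_model(kcat_t = 20, K_t = 1, kcat_r = 10, K_r = 1,
#'                     rho = 300, a = 10)
#' growth_rate(mm$model, condition_slice(mm$conditions, 1), xi = c(300, 150))
growth_rate <- function(model, condition, xi) {
  condition <- as_condition(condition)
  kin <- kinetics_precompute(model)
  MI <- M_internal(model)
  mu_eval(kin, MI, condition$a, xi)
}

mu_eval <- function(kin, MI, a, xi) {
  c_int <- drop(MI %*% xi)
  tau <- 1 / rate_all(kin, a, c_int)
  terms <- xi * tau
  terms[xi == 0] <- 0                      # 0 * Inf: no flux, no protein
  denom <- sum(terms)
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  c_P <- c_int[[length(c_int)]]
  c_P / denom
}

#' Deterministic initial point for the growth program
#'
#' Draws strictly positive growth-scaled fluxes with log-uniform magnitudes
#' (deterministic given `seed`) and rescales them so the density equality
#' `sum(M_I xi) = rho` holds exactly.
#'
#' @inheritParams growth_rate
#' @param seed integer seed.
#' @return Numeric vector `xi0` (g/L).
#' @export
choose_initial_point <- function(model, condition, seed = 42) {
  condition <- as_condition(condition)
  MI <- M_internal(model)
  import <- colSums(MI)
  if (all(import <= 0))
    stop("structurally infeasible: no transport column imports mass, so sum(M_I xi) = rho is unreachable",
         call. = FALSE)
  xi_raw <- with_seed(seed, exp(stats::runif(n_reactions(model), log(0.05), log(1))))
  s <- condition$rho / sum(import * xi_raw)
  if (!is.finite(s) || s <= 0) {
    # fallback: weight on importing columns only
    xi_raw <- ifelse(import > 0, xi_raw, xi_raw * 1e-3)
    s <- condition$rho / sum(import * xi_raw)
    if (!is.finite(s) || s <= 0)
      stop("could not rescale the initial point to meet the density constraint", call. = FALSE)
  }
  stats::setNames(xi_raw * s, colnames(model$M))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

num_grad <- function(fn, x, rel_step) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    g[j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

# Augmented Lagrangian with equality h(u) = 0 and inequalities g(u) >= 0.
# Returns list(par, value, feas, converged, iterations).
auglag_minimize <- function(u0, fn, h_fun, g_fun, lower, options) {
  method <- switch(options$solver, lbfgs = "L-BFGS-B", bfgs = "BFGS",
                   neldermead = "Nelder-Mead")
  use_bounds <- method == "L-BFGS-B"
  n_g0 <- length(g_fun(u0))
  bounded <- is.finite(lower)
  g_all <- if (use_bounds) g_fun else function(u) c(g_fun(u), (u - lower)[bounded])

  lam <- 0
  m <- numeric(n_g0 + if (use_bounds) 0 else sum(bounded))
  r <- 10
  phi <- function(u) {
    f <- fn(u)
    hv <- h_fun(u)
    gv <- g_all(u)
    pen_in <- sum((pmax(0, m - r * gv)^2 - m^2)) / (2 * r)
    f + lam * hv + (r / 2) * hv^2 + pen_in
  }
  u <- u0
  total_iter <- 0L
  f_prev <- Inf
  viol_prev <- Inf
  converged <- FALSE
  inner_maxit <- max(50L, options$maxit %/% 10L)
  for (outer in 1:25) {
    ctrl <- if (method == "L-BFGS-B")
      list(maxit = inner_maxit, factr = 1e3, pgtol = 1e-10)
    else list(maxit = inner_maxit, reltol = 1e-12)
    res <- tryCatch(
      if (use_bounds)
        stats::optim(u, phi, gr = function(x) num_grad(phi, x, options$grad_step),
                     method = method, lower = lower, control = ctrl)
      else if (method == "BFGS")
        stats::optim(u, phi, gr = function(x) num_grad(phi, x, options$grad_step),
                     method = method, control = ctrl)
      else stats::optim(u, phi, method = method, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) break
    u <- res$par
    total_iter <- total_iter + inner_maxit
    hv <- h_fun(u)
    gv <- g_all(u)
    viol <- max(abs(hv), -min(c(gv, 0)))
    f_cur <- fn(u)
    if (viol <= options$tol_constraint &&
        abs(f_cur - f_prev) <= options$tol_obj * (abs(f_cur) + 1e-12)) {
      converged <- TRUE
      break
    }
    lam <- lam + r * hv
    m <- pmax(0, m - r * gv)
    if (viol > 0.25 * viol_prev) r <- min(r * 10, 1e8)
    viol_prev <- viol
    f_prev <- f_cur
    if (total_iter >= options$maxit) break
  }
  hv <- h_fun(u)
  gv <- g_all(u)
  list(par = u, value = fn(u),
       feas = max(abs(hv), -min(c(gv, 0))),
       converged = converged && max(abs(hv), -min(c(gv, 0))) <= options$tol_constraint,
       iterations = total_iter)
}

#' Solve one growth condition
#'
#' Maximizes the balanced growth rate over growth-scaled fluxes subject to
#' the density equality, non-negative internal concentrations, non-negative
#' protein demands, and irreversibility bounds, using an
#' augmented-Lagrangian method with multistart. Non-convergence is reported
#' in the returned object (`converged = FALSE` with the best iterate), never
#' raised.
#'
#' @inheritParams growth_rate
#' @param options a [gba_options] list.
#' @param warm_start optional `xi` vector used as an additional start.
#' @return An object of class `gba_solution`: growth rate `mu` (h^-1),
#'   growth-scaled fluxes `xi` (g/L), fluxes `v = mu * xi` (g/L/h), internal
#'   concentrations `c` (g/L), protein concentrations `p` (g/L), proteome
#'   fractions `phi`, plus `converged`, `constraint_residuals`,
#'   `solver_used`, `n_iterations`.
#' @export
#' @examples
#' mm <- minimal_model(kcat_t = 20, K_t = 1, kcat_r = 10, K_r = 1,
#'                     rho = 300, a = 10)
#' sol <- solve_condition(mm$model, condition_slice(mm$conditions, 1),
#'                        gba_options(n_starts = 2))
#' sol$mu
solve_condition <- function(model, condition, options = gba_options(),
                            warm_start = NULL) {
  condition <- as_condition(condition)
  kin <- kinetics_precompute(model)
  MI <- M_internal(model)
  rho <- condition$rho
  a <- condition$a
  n <- n_reactions(model)
  irrev <- model$kcat_b == 0
  rev_idx <- which(!irrev)
  n_int <- nrow(MI)
  col_int_sum <- colSums(MI)

  # Scaled problem in u = xi / rho. The density equality sum(M_I xi) = rho
  # is eliminated exactly: every candidate is projected onto the constraint
  # surface by the positive rescaling u -> u / (1' M_I u), which preserves
  # irreversibility bounds and all sign constraints. The augmented
  # Lagrangian then only carries the inequality constraints.
  proj <- function(u) {
    s <- sum(col_int_sum * u)
    if (!is.finite(s) || s <= 1e-12) return(NULL)
    u / s
  }
  fn <- function(u) {
    w <- proj(u)
    if (is.null(w)) return(1e6)
    mu <- mu_eval(kin, MI, a, rho * w)
    if (!is.finite(mu)) return(1e6)
    -mu
  }
  h_fun <- function(u) 0
  g_fun <- function(u) {
    w <- proj(u)
    if (is.null(w)) return(rep(-1, n_int + length(rev_idx)))
    cu <- drop(MI %*% w)                      # c / rho
    g <- cu
    if (length(rev_idx)) {
      tau <- 1 / rate_all(kin, a, rho * cu)
      g <- c(g, ifelse(is.finite(tau[rev_idx]), w[rev_idx] * tau[rev_idx], -1))
    }
    g
  }
  lower <- ifelse(irrev, 0, -Inf)

  starts <- list()
  if (!is.null(warm_start)) starts <- c(starts, list(unname(warm_start) / rho))
  for (s in seq_len(options$n_starts)) {
    xi0 <- tryCatch(
      choose_initial_point(model, condition, seed = options$seed + s - 1L),
      error = function(e) e)
    if (inherits(xi0, "error")) stop(xi0)
    starts <- c(starts, list(unname(xi0) / rho))
  }

  best <- NULL
  total_iter <- 0L
  for (i in seq_along(starts)) {
    res <- auglag_minimize(starts[[i]], fn, h_fun, g_fun, lower, options)
    total_iter <- total_iter + res$iterations
    cand <- list(u = res$par, mu = -res$value, feas = res$feas,
                 converged = res$converged, start = i)
    if (is.null(best)) { best <- cand; next }
    better <-
      (cand$converged && !best$converged) ||
      (cand$converged == best$converged &&
         (cand$mu > best$mu + 1e-12 * abs(best$mu) ||
            (abs(cand$mu - best$mu) <= 1e-12 * abs(best$mu) &&
               cand$feas < best$feas)))
    if (better) best <- cand
  }

  u_star <- proj(best$u)
  if (is.null(u_star)) u_star <- best$u      # infeasible best: report raw
  xi <- stats::setNames(rho * u_star, colnames(model$M))
  build_solution(model, kin, MI, condition, xi, best$converged,
                 options, total_iter)
}

build_solution <- function(model, kin, MI, condition, xi, converged,
                           options, n_iterations) {
  rho <- condition$rho
  c_int <- stats::setNames(drop(MI %*% xi), rownames(MI))
  tau <- 1 / rate_all(kin, condition$a, c_int)
  mu <- mu_eval(kin, MI, condition$a, xi)
  if (!is.finite(mu)) {
    mu <- NA_real_
    converged <- FALSE
  }
  v <- mu * xi
  p <- v * tau
  p[xi == 0] <- 0
  c_P <- c_int[[length(c_int)]]
  phi <- if (is.finite(c_P) && c_P > 0) p / c_P else rep(NA_real_, length(p))
  residuals <- c(
    density = abs(sum(c_int) - rho),
    min_c = min(c_int),
    min_p = if (all(is.finite(p))) min(p) else NA_real_,
    protein_closure = abs(sum(p) - c_P),
    dilution = if (is.finite(mu)) max(abs(drop(MI %*% v) - mu * c_int)) else NA_real_)
  structure(list(
    mu = mu, xi = xi, v = v, c = c_int, p = p, phi = phi,
    converged = isTRUE(converged) &&
      residuals[["density"]] <= options$tol_constraint * rho &&
      residuals[["min_c"]] >= -options$tol_constraint * rho,
    constraint_residuals = residuals,
    solver_used = paste0("auglag+", options$solver),
    n_iterations = n_iterations,
    condition = condition$label),
    class = "gba_solution")
}

#' @export
print.gba_solution <- function(x, ...) {
  cat(sprintf("GBA solution [%s]: mu = %.6g /h (%s, %s)\n",
              x$condition %||% "?", x$mu,
              if (x$converged) "converged" else "NOT converged",
              x$solver_used))
  cat("  fluxes v (g/L/h):", paste(sprintf("%s=%.4g", names(x$v), x$v), collapse = ", "), "\n")
  cat("  concentrations c (g/L):", paste(sprintf("%s=%.4g", names(x$c), x$c), collapse = ", "), "\n")
  cat("  proteome fractions phi:", paste(sprintf("%s=%.3f", names(x$phi), x$phi), collapse = ", "), "\n")
  invisible(x)
}

#' Solve all growth conditions of a model
#'
#' Conditions are solved in column order; each condition warm-starts from the
#' previous converged solution. Per-condition failures are recorded in the
#' corresponding solution, and the remaining conditions still run.
#'
#' @param model a validated [gba_model].
#' @param conditions a [gba_conditions].
#' @param options a [gba_options] list; `progress` controls per-condition
#'   logging.
#' @return An object of class `gba_results`: list with `solutions` (one
#'   [solve_condition()] result per condition, order preserved), `model`,
#'   `conditions`, `options`, and `elapsed` (seconds per condition,
#'   informational).
#' @export
#' @examples
#' ex <- gba_example()
#' res <- solve_all(ex$model, ex$conditions, gba_options(n_starts = 2))
#' sapply(res$solutions, `[[`, "mu")
solve_all <- function(model, conditions, options = gba_options()) {
  n <- n_conditions(conditions)
  solutions <- vector("list", n)
  elapsed <- numeric(n)
  warm <- NULL
  notify <- if (is.function(options$progress)) options$progress
    else if (isTRUE(options$progress))
      function(label, k, n, mu) message(sprintf("[%d/%d] %s: mu = %.6g /h", k, n, label, mu))
    else function(...) invisible(NULL)
  for (k in seq_len(n)) {
    cond <- condition_slice(conditions, k)
    t0 <- proc.time()[["elapsed"]]
    sol <- tryCatch(
      solve_condition(model, cond, options, warm_start = warm),
      error = function(e) structure(list(
        mu = NA_real_, xi = NULL, v = NULL, c = NULL, p = NULL, phi = NULL,
        converged = FALSE, constraint_residuals = c(error = NA_real_),
        solver_used = paste0("auglag+", options$solver), n_iterations = 0L,
        condition = cond$label, error = conditionMessage(e)),
        class = "gba_solution"))
    elapsed[k] <- proc.time()[["elapsed"]] - t0
    solutions[[k]] <- sol
    if (isTRUE(sol$converged)) warm <- sol$xi
    notify(cond$label, k, n, sol$mu)
  }
  structure(list(solutions = solutions, model = model,
                 conditions = conditions, options = options,
                 elapsed = elapsed),
            class = "gba_results")
}

#' @export
print.gba_results <- function(x, ...) {
  mus <- vapply(x$solutions, function(s) s$mu %||% NA_real_, numeric(1))
  conv <- vapply(x$solutions, function(s) isTRUE(s$converged), logical(1))
  cat(sprintf("GBA results: %d condition(s), %d converged\n",
              length(mus), sum(conv)))
  print(data.frame(condition = condition_labels(x$conditions),
                   mu = mus, converged = conv, row.names = NULL))
  invisible(x)
}
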
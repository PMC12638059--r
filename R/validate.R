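# "Check Model" pipeline: data integrity, dimensional consistency,
# non-negativity, mass conservation, Michaelis-constant repair, size limit.
# Individual checks return results, never throw; check_model() aggregates.

check_result <- function(name, status, messages = character(0)) {
  list(name = name, status = status, messages = as.character(messages))
}

#' Check a GBA model for missing or non-numeric values
#'
#' Scans every parameter matrix and the conditions for `NA` or non-finite
#' entries and reports each offending cell by (matrix, row label, column
#' label). Failures are results, not errors.
#'
#' @param model a [gba_model].
#' @param conditions a [gba_conditions].
#' @return A check result: list with `name`, `status` (`"pass"`/`"fail"`),
#'   `messages`.
#' @export
check_data_integrity <- function(model, conditions) {
  msgs <- character(0)
  scan <- function(X, label) {
    if (is.null(dim(X))) {
      idx <- which(!is.finite(X))
      return(sprintf("%s[%s]: missing or non-numeric", label,
                     if (!is.null(names(X))) names(X)[idx] else idx))
    }
    bad <- which(!is.finite(X), arr.ind = TRUE)
    if (nrow(bad) == 0) return(character(0))
    sprintf("%s[%s, %s]: missing or non-numeric", label,
            (rownames(X) %||% seq_len(nrow(X)))[bad[, 1]],
            (colnames(X) %||% seq_len(ncol(X)))[bad[, 2]])
  }
  for (nm in c("M", "K", "KA", "KI")) msgs <- c(msgs, scan(model[[nm]], nm))
  msgs <- c(msgs, scan(model$kcat_f, "kcat_f"), scan(model$kcat_b, "kcat_b"))
  msgs <- c(msgs, scan(conditions$rho, "rho"))
  if (nrow(conditions$a)) msgs <- c(msgs, scan(conditions$a, "conditions"))
  check_result("data_integrity", if (length(msgs)) "fail" else "pass", msgs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check dimensional consistency of a GBA model
#'
#' All parameter matrices must agree with `M` on the number of reactions and
#' reactants; `KA`/`KI` must cover exactly the internal rows; the conditions
#' must carry one concentration row per `"x_"` reactant of `M`.
#'
#' @inheritParams check_data_integrity
#' @return A check result.
#' @export
check_dimensions <- function(model, conditions) {
  msgs <- character(0)
  n_rxn <- n_reactions(model)
  if (!identical(dim(model$K), dim(model$M)))
    msgs <- c(msgs, sprintf("K is %dx%d but M is %dx%d",
                            nrow(model$K), ncol(model$K), nrow(model$M), n_rxn))
  int <- internal_labels(model)
  for (nm in c("KA", "KI")) {
    X <- model[[nm]]
    if (ncol(X) != n_rxn || !identical(rownames(X), int))
      msgs <- c(msgs, sprintf("%s must span the %d internal reactant rows and %d reaction columns of M",
                              nm, length(int), n_rxn))
  }
  if (length(model$kcat_f) != n_rxn || length(model$kcat_b) != n_rxn)
    msgs <- c(msgs, sprintf("kcat must have %d columns (one per reaction)", n_rxn))
  ext <- external_labels(model)
  cond_ext <- rownames(conditions$a)
  if (nrow(conditions$a) != length(ext) ||
      (!is.null(cond_ext) && !identical(cond_ext, ext))) {
    extra <- setdiff(cond_ext, ext)
    missing <- setdiff(ext, cond_ext)
    msgs <- c(msgs, sprintf(
      "conditions must carry exactly the external reactants of M%s%s",
      if (length(extra)) paste0("; not in M: ", paste(extra, collapse = ", ")) else "",
      if (length(missing)) paste0("; absent: ", paste(missing, collapse = ", ")) else ""))
  }
  check_result("dimensions", if (length(msgs)) "fail" else "pass", msgs)
}

#' Check sign constraints on conditions
#'
#' Cell density must be strictly positive and every external concentration
#' non-negative, in every growth condition.
#'
#' @inheritParams check_data_integrity
#' @return A check result.
#' @export
check_nonnegativity <- function(model, conditions) {
  msgs <- character(0)
  bad_rho <- which(!(conditions$rho > 0))
  if (length(bad_rho))
    msgs <- c(msgs, sprintf("rho must be positive; condition %s has rho = %g",
                            condition_labels(conditions)[bad_rho],
                            conditions$rho[bad_rho]))
  if (nrow(conditions$a)) {
    bad <- which(conditions$a < 0, arr.ind = TRUE)
    if (nrow(bad))
      msgs <- c(msgs, sprintf("negative external concentration: %s in condition %s",
                              rownames(conditions$a)[bad[, 1]],
                              colnames(conditions$a)[bad[, 2]]))
  }
  check_result("nonnegativity", if (length(msgs)) "fail" else "pass", msgs)
}

#' Check the mass-fraction column sums of M
#'
#' Mass conservation within each reaction requires the positive entries of
#' every column of `M` to sum to 1 and the negative entries to sum to -1.
#'
#' @param model a [gba_model].
#' @param tol absolute tolerance on each column sum (spreadsheet-precision
#'   inputs).
#' @return A check result.
#' @export
check_mass_conservation <- function(model, tol = 1e-6) {
  M <- model$M
  pos <- colSums(M * (M > 0))
  neg <- colSums(M * (M < 0))
  bad <- which(abs(pos - 1) > tol | abs(neg + 1) > tol)
  msgs <- sprintf("column %s: positive entries sum to %.9g (need 1), negative to %.9g (need -1)",
                  colnames(M)[bad], pos[bad], neg[bad])
  check_result("mass_conservation", if (length(bad)) "fail" else "pass", msgs)
}

#' Repair zero Michaelis constants of substrates
#'
#' Every reactant consumed by a reaction (negative entry of `M`) enters the
#' saturation term of that reaction's rate law and therefore needs a positive
#' Michaelis constant. Cells where `M < 0` but `K == 0` receive the default
#' low value of 0.1 g/L. For reversible reactions (`kcat_b > 0`) the product
#' Michaelis constants are needed as well, so zero product cells of
#' reversible columns are repaired identically; products of irreversible
#' reactions never enter the rate law and are left untouched.
#'
#' @param model a [gba_model].
#' @return A list with `model` (repaired copy) and `repairs` (data frame with
#'   columns `reactant`, `reaction`, `value`; zero rows when nothing needed
#'   repair).
#' @export
#' @examples
#' ex <- gba_example()
#' broken <- ex$model; broken$K["C1", "e1"] <- 0
#' repair_km_defaults(broken)$repairs
repair_km_defaults <- function(model) {
  rev_col <- matrix(model$kcat_b > 0, nrow(model$M), ncol(model$M), byrow = TRUE)
  needs_km <- model$M < 0 | (model$M > 0 & rev_col)
  fix <- which(needs_km & model$K == 0, arr.ind = TRUE)
  repairs <- data.frame(
    reactant = rownames(model$M)[fix[, 1]],
    reaction = colnames(model$M)[fix[, 2]],
    value = rep(KM_DEFAULT, nrow(fix)),
    stringsAsFactors = FALSE)
  if (nrow(fix)) model$K[fix] <- KM_DEFAULT
  list(model = model, repairs = repairs)
}

#' Validate a GBA model
#'
#' Runs the full validation pipeline in order: data integrity, dimensional
#' consistency, non-negativity, mass conservation, Michaelis-constant repair,
#' and the solver size limit (at most 20 reactions unless `allow_large`).
#' Later checks still run when earlier ones fail, where structurally
#' possible, to maximize diagnostic value. Km repair is a warning-level
#' outcome (`"repaired"`), not a failure.
#'
#' @inheritParams check_data_integrity
#' @param allow_large lift the 20-reaction size limit (the limit reflects
#'   current solver capability, not the modeling formalism).
#' @return An object of class `gba_validation`: list with `checks` (ordered
#'   list of check results), `repaired_model` (a [gba_model] when repairs
#'   were applied, otherwise `NULL`), and `is_valid` (no check failed).
#' @export
#' @examples
#' ex <- gba_example()
#' check_model(ex$model, ex$conditions)
check_model <- function(model, conditions, allow_large = FALSE) {
  checks <- list()
  run <- function(fn, name) {
    tryCatch(fn(), error = function(e)
      check_result(name, "fail", paste("check could not run:", conditionMessage(e))))
  }
  checks$integrity <- run(function() check_data_integrity(model, conditions), "data_integrity")
  checks$dimensions <- run(function() check_dimensions(model, conditions), "dimensions")
  checks$nonneg <- run(function() check_nonnegativity(model, conditions), "nonnegativity")
  checks$mass <- run(function() check_mass_conservation(model), "mass_conservation")

  km <- tryCatch(repair_km_defaults(model), error = function(e) NULL)
  if (is.null(km)) {
    checks$km <- check_result("km_repair", "fail", "check could not run")
    repaired_model <- NULL
  } else if (nrow(km$repairs)) {
    checks$km <- check_result("km_repair", "repaired", sprintf(
      "K[%s, %s] was 0 for a rate-law reactant; set to default %.1f g/L",
      km$repairs$reactant, km$repairs$reaction, km$repairs$value))
    repaired_model <- km$model
  } else {
    checks$km <- check_result("km_repair", "pass")
    repaired_model <- NULL
  }

  n_rxn <- n_reactions(model)
  checks$size <- if (n_rxn > MAX_REACTIONS && !allow_large) {
    check_result("size_limit", "fail", sprintf(
      "model has %d reactions; the solver is limited to coarse-grained models of at most %d",
      n_rxn, MAX_REACTIONS))
  } else {
    check_result("size_limit", "pass")
  }

  structure(list(
    checks = unname(checks),
    repaired_model = repaired_model,
    is_valid = !any(vapply(checks, function(ch) ch$status == "fail", logical(1)))),
    class = "gba_validation")
}

#' @export
print.gba_validation <- function(x, ...) {
  cat("GBA model validation:", if (x$is_valid) "VALID" else "INVALID", "\n")
  for (ch in x$checks) {
    cat(sprintf("  [%s] %s\n", toupper(ch$status), ch$name))
    for (m in ch$messages) cat("      -", m, "\n")
  }
  if (!is.null(x$repaired_model))
    cat("  repaired model available in $repaired_model\n")
  invisible(x)
}

validation_to_list <- function(x) {
  list(is_valid = x$is_valid,
       repaired = !is.null(x$repaired_model),
       checks = lapply(x$checks, function(ch)
         list(name = ch$name, status = ch$status, messages = ch$messages)))
}
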
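# Result serialization, condition-sweep plots, and flux-map export.

#' Write solver results as tidy tables
#'
#' Emits `growth_rates.tsv` (condition, mu, converged), and reaction- or
#' reactant-by-condition tables `fluxes.tsv`, `proteins.tsv`,
#' `protein_fractions.tsv`, `concentrations.tsv`, plus `summary.json`
#' capturing the solver options, residuals, and seed. Numbers are written
#' with 15 significant digits so the files reproduce the in-memory values.
#'
#' @param bundle a `gba_results` object from [solve_all()].
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gba_results"), length(bundle$solutions) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- condition_labels(bundle$conditions)
  sols <- bundle$solutions

  num <- function(x) formatC(x, digits = 15, format = "g")
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }

  emit(data.frame(
    condition = labels,
    mu = num(vapply(sols, function(s) s$mu %||% NA_real_, numeric(1))),
    converged = vapply(sols, function(s) isTRUE(s$converged), logical(1))),
    "growth_rates.tsv")

  wide <- function(field, id_col, id_labels) {
    vals <- lapply(sols, function(s) {
      v <- s[[field]]
      if (is.null(v)) rep(NA_real_, length(id_labels)) else v
    })
    df <- data.frame(id_labels, lapply(vals, num), check.names = FALSE)
    names(df) <- c(id_col, labels)
    df
  }
  rxn <- colnames(bundle$model$M)
  int <- internal_labels(bundle$model)
  emit(wide("v", "reaction", rxn), "fluxes.tsv")
  emit(wide("p", "reaction", rxn), "proteins.tsv")
  emit(wide("phi", "reaction", rxn), "protein_fractions.tsv")
  emit(wide("c", "reactant", int), "concentrations.tsv")

  summary <- list(
    options = unclass(bundle$options)[setdiff(names(bundle$options), "progress")],
    conditions = labels,
    converged = vapply(sols, function(s) isTRUE(s$converged), logical(1)),
    mu = vapply(sols, function(s) s$mu %||% NA_real_, numeric(1)),
    residuals = lapply(sols, function(s) as.list(s$constraint_residuals)),
    solver_used = sols[[1]]$solver_used,
    elapsed_s = bundle$elapsed)
  path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, path)
  invisible(files)
}

#' Plot a quantity across growth conditions
#'
#' Draws one line per labeled series (reaction or reactant) over the
#' condition index: `mu` (growth rates), `c` (internal concentrations),
#' `p` (protein concentrations), `phi` (proteome fractions), or `v`
#' (fluxes). The output format follows the file extension: `.svg` or
#' `.png`.
#'
#' @param bundle a `gba_results` object covering at least two conditions.
#' @param quantity one of `"mu"`, `"c"`, `"p"`, `"phi"`, `"v"`.
#' @param path output image path ending in `.svg` or `.png`.
#' @return `path`, invisibly.
#' @export
plot_sweep <- function(bundle, quantity = c("mu", "c", "p", "phi", "v"), path) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(bundle, "gba_results"))
  n <- length(bundle$solutions)
  if (n < 2) stop(">=2 conditions required for a sweep plot", call. = FALSE)
  labels <- condition_labels(bundle$conditions)
  ylab <- switch(quantity,
                 mu = "growth rate mu (1/h)", c = "concentration (g/L)",
                 p = "protein concentration (g/L)", phi = "proteome fraction",
                 v = "flux (g/L/h)")
  if (quantity == "mu") {
    Y <- matrix(vapply(bundle$solutions, function(s) s$mu %||% NA_real_,
                       numeric(1)), ncol = 1)
    series <- "mu"
  } else {
    rows <- lapply(bundle$solutions, function(s) s[[quantity]])
    len <- max(vapply(rows, length, integer(1)))
    Y <- t(vapply(rows, function(v) if (is.null(v)) rep(NA_real_, len) else v,
                  numeric(len)))
    series <- names(rows[[which.max(vapply(rows, length, integer(1)))]])
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = 7, height = 5),
         png = grDevices::png(path, width = 700, height = 500),
         stop(sprintf("unsupported image format: .%s (use .svg or .png)", ext),
              call. = FALSE))
  on.exit(grDevices::dev.off())
  graphics::matplot(seq_len(n), Y, type = "b", pch = 19, lty = 1,
                    xlab = "condition", ylab = ylab, xaxt = "n",
                    main = sprintf("%s across conditions", quantity))
  graphics::axis(1, at = seq_len(n), labels = labels)
  if (length(series) > 1)
    graphics::legend("topleft", legend = series, col = seq_along(series),
                     lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(path)
}

#' Export a flux map as GraphML
#'
#' Builds the bipartite reactant/reaction graph of the model: one node per
#' reactant (node weight = concentration, g/L; external reactants weight 0)
#' and one per reaction (node weight = protein concentration), with an edge
#' for every nonzero entry of `M` weighted by the mass flux it carries,
#' `|v_alpha * M_i_alpha|` (g/L/h). Edge direction follows mass flow:
#' substrate -> reaction -> product. Zero-flux edges are retained with zero
#' weight.
#'
#' @param model a validated [gba_model].
#' @param solution a converged [solve_condition()] result (conventionally
#'   the first growth condition).
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
export_flux_map <- function(model, solution, path) {
  stopifnot(inherits(solution, "gba_solution"))
  if (!isTRUE(solution$converged))
    stop("flux map requires a converged solution", call. = FALSE)
  M <- model$M
  reactants <- rownames(M)
  reactions <- colnames(M)
  conc <- stats::setNames(rep(0, length(reactants)), reactants)
  conc[names(solution$c)] <- solution$c

  nz <- which(M != 0, arr.ind = TRUE)
  from <- ifelse(M[nz] < 0, reactants[nz[, 1]], paste0("rxn:", reactions[nz[, 2]]))
  to <- ifelse(M[nz] < 0, paste0("rxn:", reactions[nz[, 2]]), reactants[nz[, 1]])
  weight <- abs(solution$v[nz[, 2]] * M[nz])

  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight),
    directed = TRUE,
    vertices = data.frame(
      name = c(reactants, paste0("rxn:", reactions)),
      label = c(reactants, reactions),
      type = c(rep("reactant", length(reactants)), rep("reaction", length(reactions))),
      weight = c(conc, solution$p[reactions])))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
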
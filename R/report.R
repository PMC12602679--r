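#' Validate a network and summarise its structure
#'
#' Runs the structural checks: unit-transfer assumption, weakly connected
#' components, per-component bipartiteness, exact stoichiometric rank,
#' conservation vectors and deficiency.
#'
#' @param net a [reaction_network()].
#' @return list (class `network_check_report`) with fields
#'   `unit_transfer`, `n_components`, `bipartite` (overall and per
#'   component), `rank`, `conservation`, `deficiency`.
#' @export
network_check_report <- function(net) {
  chk <- check_unit_transfer(net)
  out <- list(unit_transfer = chk)
  if (!chk$ok) {
    out$error <- "unit-transfer assumption violated"
    class(out) <- "network_check_report"
    return(out)
  }
  g <- species_graph(net)
  per_comp <- lapply(seq_len(g$n_components), function(q) is_bipartite(g, q))
  out$n_components <- g$n_components
  out$component_membership <- g$component
  out$bipartite_per_component <- vapply(per_comp, `[[`, logical(1),
                                       "bipartite")
  out$bipartite <- all(out$bipartite_per_component)
  out$rank <- stoichiometric_rank(net)
  out$conservation <- conservation_vectors(net)
  out$deficiency <- deficiency(net, g)
  class(out) <- "network_check_report"
  out
}

#' @export
print.network_check_report <- function(x, ...) {
  cat("<network_check_report>\n")
  cat("  unit transfer:", x$unit_transfer$ok, "\n")
  if (x$unit_transfer$ok) {
    cat("  components:", x$n_components,
        " bipartite:", x$bipartite,
        " rank(S):", x$rank,
        " deficiency:", x$deficiency, "\n")
  }
  invisible(x)
}

#' Full MFPT bound analysis for one level function
#'
#' Orchestrates the pipeline: projected state space, sparse generator, level
#' decomposition, per-level rate extrema, the four closed-form bounds, and
#' (optionally) exact MFPTs between the extreme level sets by sparse linear
#' solve.  Exact values are computed from every state of the starting level
#' set; the range is reported.
#'
#' @param net a unit-transfer [reaction_network()] with an initial state.
#' @param L a `coclique_level_function`, or an index into
#'   [enumerate_level_functions()] output, or an integer coefficient vector
#'   (re-verified before use).
#' @param initial_state optional override of `net$initial_state`.
#' @param exact also solve for the exact MFPTs.
#' @return list (class `mfpt_analysis`) with the bound report, the level
#'   decomposition, and when requested `exact_up` / `exact_down` (ranges over
#'   starting states, NA when the direction is unreachable).
#' @examples
#' net <- scrn_cascade(alpha = 1, beta = 1, n_tot = 2)
#' fns <- enumerate_level_functions(net)
#' mfpt_analysis(net, fns[[1]])
#' @export
mfpt_analysis <- function(net, L = 1, initial_state = net$initial_state,
                          exact = TRUE) {
  space <- projected_state_space(net, initial_state)
  if (!inherits(L, "coclique_level_function")) {
    fns <- enumerate_level_functions(net)
    if (length(L) == 1 && L <= length(fns)) {
      L <- fns[[L]]
    } else if (length(L) == ncol(space$states)) {
      b <- as.numeric(L)
      signs <- as.numeric(t(space$info$vcheck) %*% b)
      if (!all(signs %in% c(-1, 1)))
        stop("supplied coefficients are not a coclique level function ",
             "(some b' v_k is not +/-1)")
      L <- .make_level_function(b, signs, space$info$coord_species)
    } else {
      stop("L must be a level function, a valid index, or a coefficient ",
           "vector of projected dimension")
    }
  }
  gen <- projected_generator(net, space)
  decomp <- level_decomposition(L, space, gen)
  summ <- level_rate_summary(L, space, gen, decomp)
  bounds <- mfpt_bounds(summ)
  out <- list(level_function = L, space = space, generator = gen,
              decomposition = decomp, summary = summ, bounds = bounds)
  if (exact) {
    bottom <- decomp$sets[[as.character(decomp$l)]]
    top <- decomp$sets[[as.character(decomp$u)]]
    out$exact_up <- tryCatch(
      exact_mfpt(gen$Q, target = top, start = bottom),
      error = function(e) NA_real_)
    out$exact_down <- tryCatch(
      exact_mfpt(gen$Q, target = bottom, start = top),
      error = function(e) NA_real_)
  }
  class(out) <- "mfpt_analysis"
  out
}

#' @export
print.mfpt_analysis <- function(x, ...) {
  print(x$level_function)
  print(x$bounds)
  if (!is.null(x$exact_up))
    cat("  exact bottom -> top:", paste(signif(x$exact_up, 6),
                                        collapse = ", "), "\n")
  if (!is.null(x$exact_down))
    cat("  exact top -> bottom:", paste(signif(x$exact_down, 6),
                                        collapse = ", "), "\n")
  invisible(x)
}

# serialize a level function for JSON reports
.lf_to_list <- function(f) {
  list(coefficients = as.numeric(f$b),
       coordinates = f$coord_species,
       edge_signs = as.numeric(f$signs),
       plus_set = as.integer(f$plus_set),
       minus_set = as.integer(f$minus_set))
}

#' JSON enumeration report
#'
#' Serialises the structural checks and all canonical coclique level
#' functions of a network to a versioned JSON report.
#'
#' @param net a [reaction_network()].
#' @param path optional output file; when NULL the report list is returned.
#' @return the report list, invisibly when written to file.
#' @export
enumeration_report <- function(net, path = NULL) {
  chk <- network_check_report(net)
  rep <- list(report_version = 1,
              unit_transfer = chk$unit_transfer$ok)
  if (chk$unit_transfer$ok) {
    fns <- enumerate_level_functions(net)
    rep$n_components <- chk$n_components
    rep$bipartite <- chk$bipartite
    rep$rank <- chk$rank
    rep$deficiency <- chk$deficiency
    rep$n_level_structures <- length(fns)
    rep$level_functions <- lapply(fns, .lf_to_list)
    if (!chk$bipartite)
      rep$note <- "some component is non-bipartite; no level structure exists"
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
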
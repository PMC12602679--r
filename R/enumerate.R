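# Internal projection bookkeeping shared by the enumeration and the projected
# chain.  Species are relabelled contiguously by weakly connected component
# (components ordered by smallest original species index, species keeping
# their declared relative order within a component); the last species of each
# component is eliminated, and singleton components contribute no projected
# coordinate.  `perm` maps relabelled position -> original species index.
projection_info <- function(net, g = species_graph(net)) {
  comp <- g$component
  perm <- integer(0)
  blocks <- list()        # per component: relabelled positions
  coord_of <- list()      # per component: projected coordinate indices
  coord_species <- character(0)
  pos <- 0L
  next_coord <- 0L
  for (q in seq_len(g$n_components)) {
    members <- which(comp == q)       # already in declared order
    perm <- c(perm, members)
    blocks[[q]] <- seq.int(pos + 1L, pos + length(members))
    if (length(members) > 1) {
      idx <- seq.int(next_coord + 1L, next_coord + length(members) - 1L)
      coord_of[[q]] <- idx
      coord_species <- c(coord_species,
                         net$species[members[-length(members)]])
      next_coord <- next_coord + length(members) - 1L
    } else {
      coord_of[[q]] <- integer(0)
    }
    pos <- pos + length(members)
  }
  # projected reaction vectors: length d - p
  n <- ncol(net$V)
  vcheck <- matrix(0, nrow = next_coord, ncol = n)
  for (k in seq_len(n)) {
    v <- net$V[perm, k]
    out <- numeric(next_coord)
    for (q in seq_len(g$n_components)) {
      b <- blocks[[q]]
      if (length(b) > 1)
        out[coord_of[[q]]] <- v[b[-length(b)]]
    }
    vcheck[, k] <- out
  }
  list(perm = perm, blocks = blocks, coord_of = coord_of,
       coord_species = coord_species, n_coord = next_coord,
       vcheck = vcheck, graph = g)
}

#' Reduced reaction-vector set
#'
#' A maximal subset of the reaction-vector indices containing no antiparallel
#' pair: for each pair `v_k = -v_k'` only the lower-index member is kept;
#' unpaired vectors are all kept.
#'
#' @param net a unit-transfer [reaction_network()].
#' @param g optional precomputed [species_graph()].
#' @return integer vector of kept vector indices.
#' @export
reduced_vector_set <- function(net, g = species_graph(net)) {
  keep <- logical(nrow(g$edges))
  for (k in seq_len(nrow(g$edges))) {
    keep[k] <- is.na(g$pair[k]) || k < g$pair[k]
  }
  which(keep)
}

#' Solve the coefficient system for an edge partition
#'
#' For a weakly connected unit-transfer network and a partition of its edges
#' into E+ and E-, solves the system \eqn{\check S^T b = w} exactly over the
#' rationals, where `w` is +1 on E+ and -1 on E- and \eqn{\check S} drops the
#' last species row.  The system has either no solution or a unique one, and
#' any solution has integer entries; both facts are asserted.
#'
#' @param net a unit-transfer [reaction_network()] whose graph is weakly
#'   connected (for multi-component networks call per component via
#'   [enumerate_level_functions()]).
#' @param plus_set integer indices of edges in E+ (complement goes to E-).
#' @param g optional precomputed [species_graph()].
#' @return integer coefficient vector `b` of length d-1 (named by the first
#'   d-1 species), or NULL when the system has no solution.
#' @export
solve_partition_system <- function(net, plus_set, g = species_graph(net)) {
  if (g$n_components != 1)
    stop("solve_partition_system needs a weakly connected graph; ",
         "use enumerate_level_functions() for multi-component networks")
  n <- nrow(g$edges)
  w <- rep(-1, n)
  w[plus_set] <- 1
  S <- net$V
  Scheck <- S[-nrow(S), , drop = FALSE]    # drop last species row
  b <- solve_rational(t(Scheck), w)
  if (is.null(b)) return(NULL)
  if (any(b != round(b)))
    stop("internal consistency failure: non-integer solution for a ",
         "unit-transfer partition system")
  b <- round(b)
  names(b) <- net$species[-length(net$species)]
  b
}

# canonicalize a level function: first nonzero coefficient positive
.canonical_sign <- function(b) {
  nz <- which(b != 0)
  if (length(nz) && b[nz[1]] < 0) -1 else 1
}

.make_level_function <- function(b, signs, coord_species) {
  s <- .canonical_sign(b)
  b <- b * s
  signs <- signs * s
  structure(list(b = b, signs = signs, coord_species = coord_species,
                 plus_set = which(signs == 1),
                 minus_set = which(signs == -1)),
            class = "coclique_level_function")
}

#' @export
print.coclique_level_function <- function(x, ...) {
  terms <- character(0)
  for (i in seq_along(x$b)) {
    if (x$b[i] == 0) next
    coef <- x$b[i]
    sp <- x$coord_species[i]
    terms <- c(terms,
               paste0(if (coef == 1) "" else if (coef == -1) "-" else coef,
                      if (abs(coef) > 1) "*" else "", sp))
  }
  expr <- paste(terms, collapse = " + ")
  expr <- gsub("\\+ -", "- ", expr)
  cat("<coclique_level_function> L =", expr, "\n")
  cat("  E+ = {", paste(x$plus_set, collapse = ","), "}, E- = {",
      paste(x$minus_set, collapse = ","), "}\n", sep = "")
  invisible(x)
}

# Enumerate level functions of one weakly connected component.
# Returns a list of lists with fields b (length d_q - 1, coords = component
# species minus last), signs (length n, 0 off-component), in lexicographic
# order over canonical sign assignments (+1 before -1, first reduced vector
# fixed at +1).
.enumerate_component_raw <- function(net, g, component, prune = TRUE) {
  members <- which(g$component == component)
  if (length(members) < 2) return(list())
  edge_in <- which(g$edges[, 1] %in% members)
  bip <- is_bipartite(g, component)
  if (!bip$bipartite) return(list())

  # component sub-stoichiometry: rows = member species minus last, columns =
  # component edges
  Scomp <- net$V[members, edge_in, drop = FALSE]
  Scheck <- Scomp[-nrow(Scomp), , drop = FALSE]

  vhat_global <- intersect(reduced_vector_set(net, g), edge_in)
  free <- vhat_global[-1]                       # first reduced vector fixed +1
  cycles <- if (prune) {
    all_cycles <- cycle_basis_vectors(g)
    Filter(function(th) any(th[edge_in] != 0), all_cycles)
  } else list()

  extend_signs <- function(sig_hat) {
    # sig_hat named by vhat_global; antiparallel partner gets opposite sign
    w <- numeric(nrow(g$edges))
    w[vhat_global] <- sig_hat
    for (k in vhat_global) {
      if (!is.na(g$pair[k])) w[g$pair[k]] <- -w[k]
    }
    w
  }

  out <- list()
  n_free <- length(free)
  for (mask in seq_len(2^n_free) - 1L) {
    # lexicographic: leftmost free vector varies slowest, +1 first
    sig_hat <- c(1, if (n_free)
      1 - 2 * ((mask %/% 2^((n_free - 1):0)) %% 2))
    w <- extend_signs(sig_hat)
    if (prune && partition_obstructed(w[edge_in], lapply(cycles, function(th)
      th[edge_in]))) next
    b <- solve_rational(t(Scheck), w[edge_in])
    if (is.null(b)) next
    if (any(b != round(b)))
      stop("internal consistency failure: non-integer partition solution")
    out[[length(out) + 1L]] <- list(b = round(b), signs = w,
                                    edge_in = edge_in)
  }
  out
}

#' Enumerate coclique level functions of one weakly connected component
#'
#' Iterates the `2^(|Vhat|-1)` canonical sign assignments over the reduced
#' vector set (first reduced vector fixed at +1, antiparallel partners given
#' the opposite sign), solves each coefficient system exactly, and returns
#' the solutions in lexicographic order over sign assignments.  A
#' non-bipartite component yields an empty list.
#'
#' @param net a unit-transfer [reaction_network()].
#' @param component component label (default 1).
#' @param g optional precomputed [species_graph()].
#' @param prune use the cycle-obstruction certificate as a fast path
#'   (correctness does not depend on it).
#' @return list of `coclique_level_function` objects whose coordinates are the
#'   component's species minus its last one.
#' @export
enumerate_component <- function(net, component = 1, g = species_graph(net),
                                prune = TRUE) {
  raw <- .enumerate_component_raw(net, g, component, prune)
  members <- which(g$component == component)
  coord_species <- net$species[members[-length(members)]]
  lapply(raw, function(r) {
    f <- .make_level_function(r$b, r$signs[r$edge_in], coord_species)
    f$signs_global <- r$signs * .canonical_sign(r$b)
    f
  })
}

#' Bipartite shortcut level function for one component
#'
#' For a bipartite component with two-coloring (B, C), the indicator of the
#' B-vertices (restricted to the projected coordinates) is a coclique level
#' function.  The construction internally relabels the component so that B
#' comes first; the returned coefficients live on the component's declared
#' coordinate order and the implied permutation is reported.
#'
#' @param net a unit-transfer [reaction_network()].
#' @param component component label.
#' @param g optional precomputed [species_graph()].
#' @return a `coclique_level_function` on the component's projected
#'   coordinates, with attribute `relabel` giving the B-first species
#'   permutation used by the construction.
#' @export
bipartite_level_function <- function(net, component = 1,
                                     g = species_graph(net)) {
  members <- which(g$component == component)
  if (length(members) < 2) stop("component has a single vertex")
  bip <- is_bipartite(g, component)
  if (!bip$bipartite)
    stop("component is not bipartite; no coclique level function exists")
  # indicator of B on the projected coordinates (component minus last species)
  proj <- members[-length(members)]
  b <- as.numeric(proj %in% bip$B)
  # drop-last convention: if the eliminated species is in B, use 1 - indicator
  # of C instead?  No: L(x) = sum_{i in B} x_i restricted to the projected
  # coordinates is only a level function when expressed in those coordinates;
  # if the last species lies in B, substitute x_last = tot - sum(others):
  # constants do not affect level differences, so use -indicator(C) there.
  last <- members[length(members)]
  if (last %in% bip$B) b <- -(as.numeric(proj %in% bip$C))
  edge_in <- which(g$edges[, 1] %in% members)
  Scomp <- net$V[members, edge_in, drop = FALSE]
  Scheck <- Scomp[-nrow(Scomp), , drop = FALSE]
  signs <- as.numeric(t(Scheck) %*% b)
  if (!all(signs %in% c(-1, 1)))
    stop("internal error: bipartite construction failed level-function check")
  f <- .make_level_function(b, signs, net$species[proj])
  attr(f, "relabel") <- c(members[members %in% bip$B],
                          members[members %in% bip$C])
  f
}

#' Compose per-component level functions
#'
#' Every coclique level function of a multi-component network is a signed sum
#' of per-component level functions over the multi-vertex components
#' (singleton components contribute nothing).  All sign/choice combinations
#' are formed and deduplicated under global negation; the canonical
#' representative fixes the sign of the first multi-vertex component.
#'
#' @param per_component list (over multi-vertex components, in component
#'   order) of lists of `coclique_level_function`s as returned by
#'   [enumerate_component()].
#' @param info projection info (internal); supply `net` instead in normal use
#'   via [enumerate_level_functions()].
#' @return list of composed `coclique_level_function`s on the full projected
#'   coordinates; empty when any multi-vertex component has none.
#' @keywords internal
compose_components <- function(per_component, info) {
  multi <- which(vapply(info$coord_of, length, integer(1)) > 0)
  if (length(per_component) != length(multi))
    stop("per_component must have one list per multi-vertex component")
  if (any(vapply(per_component, length, integer(1)) == 0)) return(list())

  n <- ncol(info$vcheck)
  choices <- lapply(per_component, seq_along)
  sign_opts <- rep(list(c(1, -1)), length(multi))
  sign_opts[[1]] <- 1                # canonical: first component sign fixed
  grid_choice <- expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)
  grid_sign <- expand.grid(rev(sign_opts), KEEP.OUT.ATTRS = FALSE)
  out <- list()
  seen <- character(0)
  for (ci in seq_len(nrow(grid_choice))) {
    choice <- rev(as.integer(grid_choice[ci, ]))
    for (si in seq_len(nrow(grid_sign))) {
      sgn <- rev(as.numeric(grid_sign[si, ]))
      b <- numeric(info$n_coord)
      for (m in seq_along(multi)) {
        q <- multi[m]
        f <- per_component[[m]][[choice[m]]]
        b[info$coord_of[[q]]] <- sgn[m] * f$b
      }
      signs <- as.numeric(t(info$vcheck) %*% b)
      if (!all(signs %in% c(-1, 1)))
        stop("internal error: composed function fails the level check")
      key <- paste(b * .canonical_sign(b), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- .make_level_function(b, signs,
                                                      info$coord_species)
    }
  }
  out
}

#' Enumerate all coclique level functions of a network
#'
#' Top-level enumeration: builds the species graph, enumerates each
#' multi-vertex weakly connected component (empty for non-bipartite
#' components), and composes the per-component functions into level functions
#' on the full projected state space.  Output is canonical (first nonzero
#' coefficient positive) and deduplicated under negation, so each entry is
#' one distinct coclique level structure.
#'
#' @param net a unit-transfer [reaction_network()].
#' @param prune use the cycle-obstruction fast path.
#' @return list of `coclique_level_function` objects; empty when some
#'   multi-vertex component is non-bipartite.
#' @examples
#' net <- scrn_cascade(alpha = 1, beta = 1, n_tot = 2)
#' enumerate_level_functions(net)
#' @export
enumerate_level_functions <- function(net, prune = TRUE) {
  g <- species_graph(net)
  info <- projection_info(net, g)
  multi <- which(vapply(info$coord_of, length, integer(1)) > 0)
  if (!length(multi)) return(list())
  per_component <- lapply(multi, function(q) {
    raw <- .enumerate_component_raw(net, g, q, prune)
    members <- which(g$component == q)
    coord_species <- net$species[members[-length(members)]]
    lapply(raw, function(r)
      .make_level_function(r$b, r$signs[which(g$edges[, 1] %in% members)],
                           coord_species))
  })
  compose_components(per_component, info)
}
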
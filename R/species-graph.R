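#' Build the species graph of a unit-transfer network
#'
#' Vertices are species; edge `e_k = (i, j)` exists iff reaction vector `v_k`
#' has `v_k[i] = -1` and `v_k[j] = +1` (one edge per distinct reaction
#' vector).  Antiparallel pairs (`v_k = -v_k'`) are detected and
#' cross-indexed.  Weakly connected components are labelled 1..p in order of
#' the smallest species index they contain.
#'
#' @param net a [reaction_network()] satisfying the unit-transfer assumption.
#' @return an object of class `species_graph` with components `d`, `edges`
#'   (n x 2 matrix of (from, to) species indices), `pair` (antiparallel
#'   partner edge index or NA), `component` (vertex -> component label),
#'   `n_components`, and `igraph` (the underlying igraph object).
#' @export
species_graph <- function(net) {
  chk <- check_unit_transfer(net)
  if (!chk$ok)
    stop("network violates the unit-transfer assumption; offending reaction ",
         "vector(s): ",
         paste(apply(net$V[, chk$violations, drop = FALSE], 2, paste,
                     collapse = ","), collapse = "; "))
  V <- net$V
  d <- length(net$species)
  n <- ncol(V)
  edges <- t(vapply(seq_len(n),
                    function(k) c(which(V[, k] == -1), which(V[, k] == 1)),
                    numeric(2)))
  colnames(edges) <- c("from", "to")

  pair <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    for (k2 in seq_len(n)) {
      if (k2 != k && all(V[, k2] == -V[, k])) pair[k] <- k2
    }
  }

  g <- igraph::make_empty_graph(n = d, directed = TRUE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  comp_raw <- igraph::components(g, mode = "weak")$membership
  # relabel components by smallest member vertex
  firsts <- vapply(seq_len(max(comp_raw)),
                   function(cc) min(which(comp_raw == cc)), numeric(1))
  relabel <- match(seq_along(firsts), order(firsts))
  component <- relabel[comp_raw]

  structure(list(d = d, edges = edges, pair = pair,
                 component = component,
                 n_components = max(component),
                 igraph = g),
            class = "species_graph")
}

#' @export
print.species_graph <- function(x, ...) {
  cat("<species_graph> ", x$d, " vertices, ", nrow(x$edges), " edges, ",
      x$n_components, " weakly connected component(s)\n", sep = "")
  invisible(x)
}

#' Weakly connected components of the species graph
#'
#' @param g a [species_graph()].
#' @return list with `membership` (vertex -> component label, contiguous from
#'   1 in order of smallest member) and `count`.
#' @export
weakly_connected_components <- function(g) {
  stopifnot(inherits(g, "species_graph"))
  list(membership = g$component, count = g$n_components)
}

# undirected adjacency list of a vertex subset, antiparallel pairs collapsed
.undirected_adj <- function(g, vertices = seq_len(g$d)) {
  adj <- vector("list", g$d)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1]; j <- g$edges[k, 2]
    adj[[i]] <- unique(c(adj[[i]], j))
    adj[[j]] <- unique(c(adj[[j]], i))
  }
  adj
}

#' Bipartiteness test with deterministic two-coloring
#'
#' Tests the underlying undirected (multi)graph; antiparallel edge pairs count
#' as a single undirected edge.  The coloring is reproducible: BFS from the
#' lowest-index vertex of each component, root coloured B; neighbours visited
#' in increasing index order.
#'
#' @param g a [species_graph()].
#' @param component optional component label; default tests all components
#'   and combines.
#' @return list with `bipartite` (logical), `B` and `C` (vertex index sets;
#'   meaningful when bipartite).
#' @export
is_bipartite <- function(g, component = NULL) {
  stopifnot(inherits(g, "species_graph"))
  vertices <- if (is.null(component)) seq_len(g$d)
              else which(g$component == component)
  adj <- .undirected_adj(g)
  colour <- rep(NA_integer_, g$d)   # 1 = B, 2 = C
  ok <- TRUE
  for (root in vertices) {
    if (!is.na(colour[root]) || !(root %in% vertices)) next
    if (!is.na(colour[root])) next
    colour[root] <- 1L
    queue <- root
    while (length(queue) && ok) {
      v <- queue[1]; queue <- queue[-1]
      for (w in sort(adj[[v]])) {
        if (!(w %in% vertices)) next
        if (is.na(colour[w])) {
          colour[w] <- 3L - colour[v]
          queue <- c(queue, w)
        } else if (colour[w] == colour[v]) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) break
  }
  if (!ok) return(list(bipartite = FALSE, B = integer(0), C = integer(0)))
  list(bipartite = TRUE,
       B = vertices[colour[vertices] == 1L],
       C = vertices[colour[vertices] == 2L])
}

#' Deficiency of the species graph network
#'
#' `delta = d - p - rank(S)` where p is the number of weakly connected
#' components; rank is exact over the rationals.  Unit-transfer networks
#' always have deficiency zero.
#'
#' @param net a [reaction_network()].
#' @param g optional precomputed [species_graph()].
#' @return integer deficiency.
#' @export
deficiency <- function(net, g = species_graph(net)) {
  g$d - g$n_components - stoichiometric_rank(net)
}

#' Cycle basis vectors of the species graph
#'
#' A cycle basis of the underlying undirected multigraph (antiparallel edges
#' kept distinct), each basis cycle encoded as a signed incidence vector
#' `theta` of length n: +1 where the edge is traversed along its direction,
#' -1 against, 0 off the cycle.  Every returned vector lies in ker(S).
#' An antiparallel pair yields the 2-cycle with both entries +1.
#'
#' @param g a [species_graph()].
#' @return list of integer vectors of length n (empty when the graph is a
#'   forest).
#' @export
cycle_basis_vectors <- function(g) {
  stopifnot(inherits(g, "species_graph"))
  n <- nrow(g$edges)
  # BFS spanning forest over the undirected multigraph: tree edges recorded
  # with the edge index used to reach each vertex
  parent <- rep(NA_integer_, g$d)
  parent_edge <- rep(NA_integer_, g$d)
  visited <- rep(FALSE, g$d)
  tree_edge <- rep(FALSE, n)
  # incidence list: for each vertex, (edge index, other endpoint)
  inc <- vector("list", g$d)
  for (k in seq_len(n)) {
    i <- g$edges[k, 1]; j <- g$edges[k, 2]
    inc[[i]] <- rbind(inc[[i]], c(k, j))
    inc[[j]] <- rbind(inc[[j]], c(k, i))
  }
  for (root in seq_len(g$d)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (is.null(inc[[v]])) next
      for (r in seq_len(nrow(inc[[v]]))) {
        k <- inc[[v]][r, 1]; w <- inc[[v]][r, 2]
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          parent_edge[w] <- k
          tree_edge[k] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  # tree path from vertex a up to the root, as list of (vertex, edge) steps
  path_to_root <- function(a) {
    verts <- a; edges <- integer(0)
    while (!is.na(parent[a])) {
      edges <- c(edges, parent_edge[a])
      a <- parent[a]
      verts <- c(verts, a)
    }
    list(verts = verts, edges = edges)
  }
  cycles <- list()
  for (k in which(!tree_edge)) {
    i <- g$edges[k, 1]; j <- g$edges[k, 2]
    theta <- numeric(n)
    theta[k] <- 1          # traverse e_k along its direction i -> j
    pi_ <- path_to_root(i); pj <- path_to_root(j)
    # lowest common ancestor: first shared vertex of the two root paths
    common <- intersect(pi_$verts, pj$verts)[1]
    ci <- match(common, pi_$verts); cj <- match(common, pj$verts)
    # close the cycle j -> ... -> common -> ... -> i
    # walk j up to common: each step goes child -> parent
    v <- j
    for (s in seq_len(cj - 1)) {
      e <- pj$edges[s]
      p <- pj$verts[s + 1]
      # step v -> p; edge e is directed edges[e,1] -> edges[e,2]
      theta[e] <- theta[e] + (if (g$edges[e, 1] == v) 1 else -1)
      v <- p
    }
    # walk common down to i: reverse of i's up-path, steps parent -> child
    if (ci > 1) {
      for (s in rev(seq_len(ci - 1))) {
        e <- pi_$edges[s]
        child <- pi_$verts[s]
        p <- pi_$verts[s + 1]
        # step p -> child
        theta[e] <- theta[e] + (if (g$edges[e, 1] == p) 1 else -1)
      }
    }
    cycles[[length(cycles) + 1L]] <- theta
  }
  cycles
}

#' Weakly directed cycle obstruction test
#'
#' Given a sign vector `w` in {-1, +1}^n encoding an edge partition
#' (+1 on E+, -1 on E-), returns TRUE when some basis cycle `theta` has
#' `w . theta != 0`, which certifies that the coefficient system for this
#' partition has no solution.  On unit-transfer graphs the cycle space spans
#' ker(S), so the certificate is also complete.
#'
#' @param w integer vector of +/-1 of length n.
#' @param cycles output of [cycle_basis_vectors()].
#' @return logical.
#' @export
partition_obstructed <- function(w, cycles) {
  stopifnot(all(w %in% c(-1, 1)))
  for (theta in cycles) {
    if (sum(w * theta) != 0) return(TRUE)
  }
  FALSE
}
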
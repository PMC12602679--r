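#' Create a reaction
#'
#' A single chemical reaction with integer reactant/product stoichiometry and
#' a mass-action rate constant.  Constants are taken as already scaled for
#' reaction volume (e.g. bimolecular constants divided by V by the caller),
#' so the propensity is literally `kappa * prod((x_i)_(reactant_i))` with
#' falling-factorial powers.
#'
#' @param reactants named integer vector of reactant counts (species -> count);
#'   species not named are taken as 0.
#' @param products named integer vector of product counts.
#' @param rate non-negative mass-action rate constant.
#' @return an object of class `reaction`.
#' @examples
#' reaction(c(Z = 1), c(W = 1), rate = 0.5)
#' @export
reaction <- function(reactants, products, rate) {
  reactants <- unlist(reactants)
  products <- unlist(products)
  stopifnot(is.numeric(rate), length(rate) == 1, rate >= 0, is.finite(rate))
  for (v in list(reactants, products)) {
    if (length(v)) {
      if (is.null(names(v)) || any(!nzchar(names(v))))
        stop("stoichiometry vectors must be named by species")
      if (any(v < 0) || any(v != round(v)) || any(!is.finite(v)))
        stop("stoichiometric counts must be finite non-negative integers")
    }
  }
  structure(list(reactants = reactants, products = products, rate = rate),
            class = "reaction")
}

#' Create a stochastic chemical reaction network
#'
#' Builds the network object, computes the reaction vectors `v+ - v-`,
#' deduplicates them in order of first appearance into the vector set V with
#' its reaction grouping, and assembles the stoichiometric matrix S whose
#' columns are the distinct reaction vectors.
#'
#' @param species character vector of distinct species names; the declared
#'   order is authoritative for all coordinates downstream.
#' @param reactions list of [reaction()] objects.
#' @param initial_state optional named integer vector giving the initial copy
#'   number of each species (defines conserved totals for the projected chain).
#' @return an object of class `reaction_network` with components `species`,
#'   `reactions`, `V` (d x n matrix of distinct reaction vectors), `groups`
#'   (list mapping vector index -> reaction indices), `S` (alias of `V`), and
#'   `initial_state`.
#' @examples
#' net <- reaction_network(
#'   species = c("W", "Y", "Z"),
#'   reactions = list(
#'     reaction(c(Z = 1), c(W = 1), rate = 1),
#'     reaction(c(W = 1), c(Y = 1), rate = 1)
#'   ),
#'   initial_state = c(W = 0, Y = 0, Z = 2)
#' )
#' stoichiometric_matrix(net)
#' @export
reaction_network <- function(species, reactions, initial_state = NULL) {
  species <- as.character(species)
  d <- length(species)
  if (d < 2) stop("a network needs at least two species")
  if (anyDuplicated(species)) stop("species names must be unique")
  if (!length(reactions)) stop("a network needs at least one reaction")
  if (!all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("`reactions` must be a list of reaction() objects")

  vecs <- matrix(0, nrow = d, ncol = length(reactions),
                 dimnames = list(species, NULL))
  touched <- rep(FALSE, d)
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    unknown <- setdiff(c(names(r$reactants), names(r$products)), species)
    if (length(unknown))
      stop("unknown species in reaction ", j, ": ",
           paste(unknown, collapse = ", "))
    v <- numeric(d); names(v) <- species
    v[names(r$products)] <- v[names(r$products)] + r$products
    v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
    if (all(v == 0))
      stop("reaction ", j, " has equal reactant and product vectors")
    touched[species %in% c(names(r$reactants), names(r$products))] <- TRUE
    vecs[, j] <- v
  }
  if (!all(touched))
    stop("species never appearing in a reaction: ",
         paste(species[!touched], collapse = ", "))

  keys <- apply(vecs, 2, paste, collapse = ",")
  first <- !duplicated(keys)
  V <- vecs[, first, drop = FALSE]
  ukeys <- keys[first]
  groups <- lapply(ukeys, function(k) which(keys == k))
  colnames(V) <- NULL

  if (!is.null(initial_state)) {
    initial_state <- initial_state[species]
    if (any(is.na(initial_state)) || any(initial_state < 0) ||
        any(initial_state != round(initial_state)))
      stop("initial_state must give a non-negative integer for every species")
    names(initial_state) <- species
  }

  structure(list(species = species, reactions = reactions,
                 V = V, groups = groups, S = V,
                 initial_state = initial_state),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions, ", ncol(x$V),
      " distinct reaction vectors\n", sep = "")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Distinct reaction vectors and their reaction groups
#'
#' @param net a [reaction_network()].
#' @return list with `vectors` (d x n integer matrix, columns in order of
#'   first appearance) and `groups` (list of reaction index vectors, one per
#'   column).
#' @export
reaction_vector_set <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  list(vectors = net$V, groups = net$groups)
}

#' Stoichiometric matrix
#'
#' @param net a [reaction_network()].
#' @return integer matrix S (d x n) whose columns are the distinct reaction
#'   vectors, with species names as row names.
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  S <- net$V
  rownames(S) <- net$species
  S
}

#' Exact rank of the stoichiometric matrix
#'
#' Computed over the rationals, not in floating point.
#'
#' @param net a [reaction_network()].
#' @return integer rank.
#' @export
stoichiometric_rank <- function(net) {
  rank_rational(stoichiometric_matrix(net))
}

#' Conservation vectors
#'
#' Integer basis of the left null space \eqn{\{m : m^T S = 0\}}, each basis
#' vector scaled to gcd 1 with positive leading entry.  The basis is canonical
#' (follows the free columns of the rational RREF of \eqn{S^T}), so repeated
#' calls give identical output.
#'
#' @param net a [reaction_network()].
#' @return list with `basis` (list of integer vectors, possibly empty) and
#'   `unique` (TRUE when the left null space is one-dimensional).
#' @export
conservation_vectors <- function(net) {
  S <- stoichiometric_matrix(net)
  basis <- nullspace_rational(t(S))
  basis <- lapply(basis, function(v) { names(v) <- net$species; v })
  list(basis = basis, unique = length(basis) == 1L)
}

#' Check the unit-transfer assumption
#'
#' A network is unit-transfer when every distinct reaction vector has exactly
#' one +1 entry, one -1 entry and zeros elsewhere: each reaction converts one
#' molecule of one species into one molecule of another.
#'
#' @param net a [reaction_network()].
#' @return list with `ok` (logical) and `violations` (integer indices of the
#'   offending columns of the reaction-vector set).
#' @export
check_unit_transfer <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  V <- net$V
  bad <- integer(0)
  for (k in seq_len(ncol(V))) {
    v <- V[, k]
    if (!(sum(v == 1) == 1 && sum(v == -1) == 1 && sum(v == 0) == length(v) - 2))
      bad <- c(bad, k)
  }
  list(ok = length(bad) == 0, violations = bad)
}

#' Mass-action propensity of a single reaction
#'
#' \eqn{\kappa \prod_i (x_i)_{(v^-)_i}} with falling-factorial powers;
#' 0 whenever some reactant exceeds its available copies.
#'
#' @param rxn a [reaction()].
#' @param state non-negative integer vector of copy numbers, named by species.
#' @return non-negative propensity value.
#' @export
mass_action_propensity <- function(rxn, state) {
  stopifnot(inherits(rxn, "reaction"))
  if (any(state < 0)) stop("state entries must be non-negative")
  p <- rxn$rate
  for (sp in names(rxn$reactants)) {
    cnt <- rxn$reactants[[sp]]
    if (cnt == 0) next
    x <- state[[sp]]
    if (x < cnt) return(0)
    # falling factorial x * (x-1) * ... * (x-cnt+1)
    p <- p * prod(x - seq_len(cnt) + 1)
  }
  p
}

#' Total propensity of a reaction-vector group
#'
#' Sum of mass-action propensities over all reactions sharing reaction vector
#' `k` (the set R_{v_k}).
#'
#' @param net a [reaction_network()].
#' @param k index into the distinct reaction-vector set.
#' @param state full-dimensional state, named by species or in species order.
#' @return non-negative total rate \eqn{\Upsilon_k(x)}.
#' @export
total_propensity <- function(net, k, state) {
  stopifnot(inherits(net, "reaction_network"))
  if (k < 1 || k > length(net$groups)) stop("vector index out of range")
  if (is.null(names(state))) names(state) <- net$species
  sum(vapply(net$groups[[k]],
             function(j) mass_action_propensity(net$reactions[[j]], state),
             numeric(1)))
}

#' Read a reaction network from a JSON file
#'
#' Format: `{"species": [...], "reactions": [{"reactants": {..}, "products":
#' {..}, "rate_constant": r}, ...], "initial_state": {..}}`.
#'
#' @param path file path.
#' @return a [reaction_network()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$species) || is.null(obj$reactions))
    stop("network JSON must contain 'species' and 'reactions'")
  species <- vapply(obj$species, as.character, character(1))
  reactions <- lapply(obj$reactions, function(r) {
    reaction(reactants = unlist(r$reactants) %||% numeric(0),
             products = unlist(r$products) %||% numeric(0),
             rate = as.numeric(r$rate_constant))
  })
  init <- if (!is.null(obj$initial_state)) unlist(obj$initial_state)
  reaction_network(species, reactions, initial_state = init)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reaction network to a JSON file
#'
#' @param net a [reaction_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  obj <- list(
    species = net$species,
    reactions = lapply(net$reactions, function(r) {
      list(reactants = as.list(r$reactants),
           products = as.list(r$products),
           rate_constant = r$rate)
    })
  )
  if (!is.null(net$initial_state))
    obj$initial_state <- as.list(net$initial_state)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
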
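# Shared helpers and independent oracles for the test suite.

# a directed 3-cycle (odd cycle, not bipartite)
triangle_net <- function() {
  reaction_network(
    species = c("S1", "S2", "S3"),
    reactions = list(
      reaction(c(S1 = 1), c(S2 = 1), rate = 1),
      reaction(c(S2 = 1), c(S3 = 1), rate = 1),
      reaction(c(S3 = 1), c(S1 = 1), rate = 1)
    ),
    initial_state = c(S1 = 2, S2 = 0, S3 = 0)
  )
}

# dimerization 2 S1 -> S2: violates the unit-transfer assumption
dimer_net <- function() {
  reaction_network(
    species = c("S1", "S2"),
    reactions = list(reaction(c(S1 = 2), c(S2 = 1), rate = 1)),
    initial_state = c(S1 = 4, S2 = 0)
  )
}

two_species_net <- function(tot = 3) {
  reaction_network(
    species = c("S1", "S2"),
    reactions = list(reaction(c(S1 = 1), c(S2 = 1), rate = 1)),
    initial_state = c(S1 = tot, S2 = 0)
  )
}

# Independent brute-force enumeration oracle for one weakly connected
# component: try ALL 2^n sign vectors over the component's edges (no reduced
# set, no canonical fixing), solve each exactly, canonicalize solutions by
# making the first nonzero coefficient positive, and return the unique set of
# coefficient vectors as a sorted character vector of keys.
brute_force_component <- function(net, component = 1) {
  g <- species_graph(net)
  members <- which(g$component == component)
  edge_in <- which(g$edges[, 1] %in% members)
  n <- length(edge_in)
  Scomp <- net$V[members, edge_in, drop = FALSE]
  Scheck <- Scomp[-nrow(Scomp), , drop = FALSE]
  keys <- character(0)
  for (mask in 0:(2^n - 1)) {
    w <- 1 - 2 * ((mask %/% 2^((n - 1):0)) %% 2)
    b <- coclique:::solve_rational(t(Scheck), w)
    if (is.null(b)) next
    nz <- which(b != 0)
    if (length(nz) && b[nz[1]] < 0) b <- -b
    keys <- c(keys, paste(b, collapse = ","))
  }
  sort(unique(keys))
}

enumerated_keys <- function(fns) {
  sort(vapply(fns, function(f) paste(f$b, collapse = ","), character(1)))
}

# Exact MFPT of a birth-death chain on levels l..u by dense first-step solve;
# independent of the closed-form path it checks.
bd_exact_mfpt <- function(l, u, up, down, from_level, to_level) {
  levels <- l:u
  m <- length(levels)
  Q <- matrix(0, m, m)
  for (i in seq_len(m - 1)) Q[i, i + 1] <- up[i]
  for (i in 2:m) Q[i, i - 1] <- down[i - 1]
  diag(Q) <- -rowSums(Q)
  target <- match(to_level, levels)
  rest <- setdiff(seq_len(m), target)
  h <- solve(Q[rest, rest, drop = FALSE], rep(-1, length(rest)))
  full <- numeric(m)
  full[rest] <- h
  full[match(from_level, levels)]
}

# find the enumerated function with given coefficients
find_fn <- function(fns, b) {
  hit <- which(vapply(fns, function(f) length(f$b) == length(b) &&
                        all(f$b == b), logical(1)))
  stopifnot(length(hit) == 1)
  fns[[hit]]
}
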
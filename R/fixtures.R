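# Example networks.  Rate constants are folded the way mass-action kinetics
# with volume scaling prescribes: bimolecular constants divided by V, and
# homodimeric (2A -> ...) constants divided by 2V so the falling-factorial
# propensity kappa/(2V) * x (x - 1) matches the conventional rate
# kappa * x (x - 1) / (2V).

#' Three-species conversion cascade
#'
#' `Z -> W -> Y` with rates `alpha`, `beta`; total copy number conserved.
#' Species order (W, Y, Z), so the projected chain tracks (n_W, n_Y).
#'
#' @param alpha,beta positive rate constants.
#' @param n_tot total number of molecules, all initially Z.
#' @return a [reaction_network()].
#' @export
scrn_cascade <- function(alpha = 1, beta = 1, n_tot = 2) {
  stopifnot(alpha > 0, beta > 0, n_tot >= 1)
  reaction_network(
    species = c("W", "Y", "Z"),
    reactions = list(
      reaction(c(Z = 1), c(W = 1), rate = alpha),
      reaction(c(W = 1), c(Y = 1), rate = beta)
    ),
    initial_state = c(W = 0, Y = 0, Z = n_tot)
  )
}

#' Two independent subsystems
#'
#' `S1 <-> S2` (rates `k1`, `k2`) and `S3 -> S4` (rate `k3`): two weakly
#' connected components evolving independently.
#'
#' @param k1,k2,k3 positive rate constants.
#' @param n1,n2 conserved totals of the two components (initially all S1,
#'   all S3).
#' @return a [reaction_network()].
#' @export
scrn_two_component <- function(k1 = 1, k2 = 1, k3 = 1, n1 = 1, n2 = 1) {
  reaction_network(
    species = c("S1", "S2", "S3", "S4"),
    reactions = list(
      reaction(c(S1 = 1), c(S2 = 1), rate = k1),
      reaction(c(S2 = 1), c(S1 = 1), rate = k2),
      reaction(c(S3 = 1), c(S4 = 1), rate = k3)
    ),
    initial_state = c(S1 = n1, S2 = 0, S3 = n2, S4 = 0)
  )
}

#' Coupled two-component network with catalysts
#'
#' `S1 + S4 -> S2 + S4`, `S2 + S5 -> S1 + S5`, `S3 <-> S4`: three weakly
#' connected components (S5 isolated), with cross-component catalysis, so the
#' subsystems cannot be analysed independently.
#'
#' @param k1,k2,k3,k4 positive rate constants.
#' @param n1,n2,n3 conserved totals of the three components (initially all
#'   S1, all S3, and `n3` copies of S5).
#' @return a [reaction_network()].
#' @export
scrn_coupled <- function(k1 = 1, k2 = 1, k3 = 1, k4 = 1,
                         n1 = 2, n2 = 3, n3 = 1) {
  reaction_network(
    species = c("S1", "S2", "S3", "S4", "S5"),
    reactions = list(
      reaction(c(S1 = 1, S4 = 1), c(S2 = 1, S4 = 1), rate = k1),
      reaction(c(S2 = 1, S5 = 1), c(S1 = 1, S5 = 1), rate = k2),
      reaction(c(S3 = 1), c(S4 = 1), rate = k3),
      reaction(c(S4 = 1), c(S3 = 1), rate = k4)
    ),
    initial_state = c(S1 = n1, S2 = 0, S3 = n2, S4 = 0, S5 = n3)
  )
}

#' Histone modification circuit
#'
#' Three nucleosome states -- unmodified D, repressively modified DR,
#' activation-marked DA -- where each modification autocatalyses its own
#' establishment and catalyses erasure of the opposite one.  Species order
#' (DR, DA, D), so the projected chain tracks (n_DR, n_DA).  Derived
#' parameters follow the identities `delta_A = eps * kA_M * D_tot / V`,
#' `delta_R = delta_A * mu * b_tilde`, `kR_E = mu * kA_E`.
#'
#' @param eps timescale-separation parameter (> 0): ratio of basal erasure to
#'   autocatalytic establishment rates.
#' @param mu ratio of cross-catalysed erasure constants `kR_E / kA_E`.
#' @param b_tilde ratio `delta_R / (mu * delta_A)`.
#' @param d_tot total number of nucleosomes (initially all unmodified).
#' @param kA_W0,kA_W,kA_M,kA_E,kR_W0,kR_W,kR_M base rate constants.
#' @param V reaction volume.
#' @return a [reaction_network()].
#' @export
scrn_histone <- function(eps = 0.1, mu = 1, b_tilde = 1, d_tot = 2,
                         kA_W0 = 1, kA_W = 1, kA_M = 1, kA_E = 1,
                         kR_W0 = 1, kR_W = 1, kR_M = 1, V = 1) {
  stopifnot(eps > 0, mu > 0, b_tilde > 0, d_tot >= 1)
  delta_A <- eps * kA_M * d_tot / V
  delta_R <- delta_A * mu * b_tilde
  kR_E <- mu * kA_E
  reaction_network(
    species = c("DR", "DA", "D"),
    reactions = list(
      reaction(c(D = 1), c(DA = 1), rate = kA_W0 + kA_W),            # 1
      reaction(c(D = 1, DA = 1), c(DA = 2), rate = kA_M / V),        # 2
      reaction(c(DA = 1), c(D = 1), rate = delta_A),                 # 3
      reaction(c(DA = 1, DR = 1), c(D = 1, DR = 1), rate = kA_E / V),# 4
      reaction(c(D = 1), c(DR = 1), rate = kR_W0 + kR_W),            # 5
      reaction(c(D = 1, DR = 1), c(DR = 2), rate = kR_M / V),        # 6
      reaction(c(DR = 1), c(D = 1), rate = delta_R),                 # 7
      reaction(c(DR = 1, DA = 1), c(D = 1, DA = 1), rate = kR_E / V) # 8
    ),
    initial_state = c(DR = 0, DA = 0, D = d_tot)
  )
}

#' Full chromatin modification circuit
#'
#' Five nucleosome states: unmodified D, DNA-methylated DR1, repressive
#' histone-marked DR2, doubly repressed DR12, and activation-marked DA, with
#' cross-catalysis between DNA methylation and repressive histone marks.
#' Species order (DR12, DA, DR1, DR2, D).  Derived parameters follow
#' `delta_A = eps * kA_M * D_tot / V`, `delta_R = delta_A * mu * b_tilde`,
#' `kR_E = mu * kA_E`, `k_TT = mu_p * kA_E` (DNA methylation erasure) and
#' `delta_p + k_T = beta * mu_p * delta_A`.
#'
#' @param eps timescale-separation parameter (> 0).
#' @param mu,b_tilde repressive-histone erasure ratios as in [scrn_histone()].
#' @param mu_p ratio of DNA-methylation erasure to activating-mark erasure.
#' @param beta_p ratio tying the basal DNA-methylation erasure to `delta_A`.
#' @param d_tot total number of nucleosomes (initially all unmodified).
#' @param kA_W0,kA_W,kA_M,kA_E,k1_W0,k1_W,k2_W0,k2_W,k_M,kbar_M,kp_M base
#'   rate constants.
#' @param V reaction volume.
#' @return a [reaction_network()].
#' @export
scrn_full_chromatin <- function(eps = 0.1, mu = 1, b_tilde = 1, mu_p = 1,
                                beta_p = 1, d_tot = 2,
                                kA_W0 = 1, kA_W = 1, kA_M = 1, kA_E = 1,
                                k1_W0 = 1, k1_W = 1, k2_W0 = 1, k2_W = 1,
                                k_M = 1, kbar_M = 1, kp_M = 1, V = 1) {
  stopifnot(eps > 0, mu > 0, b_tilde > 0, mu_p > 0, beta_p > 0, d_tot >= 1)
  delta_A <- eps * kA_M * d_tot / V
  delta_R <- delta_A * mu * b_tilde
  kR_E <- mu * kA_E
  k_TT <- mu_p * kA_E                 # DA-catalysed DNA-methylation erasure
  delta_T <- beta_p * mu_p * delta_A  # basal DNA-methylation erasure
  # One reaction per circled number of the published circuit, listed so that
  # the first appearance of each distinct reaction vector follows the
  # conventional order v1..v10 (DA up/down, DR1 up/down, DR2 up/down,
  # DR1->DR12 and back, DR2->DR12 and back): the edge numbering of the
  # species graph then matches the one used to describe edge partitions.
  rx <- list(
    reaction(c(D = 1), c(DA = 1), rate = kA_W0 + kA_W),                    # 1
    reaction(c(D = 1, DA = 1), c(DA = 2), rate = kA_M / V),                # 2
    reaction(c(DA = 1), c(D = 1), rate = delta_A),                         # 3
    reaction(c(DA = 1, DR1 = 1), c(D = 1, DR1 = 1), rate = kA_E / V),      # 4
    reaction(c(DA = 1, DR12 = 1), c(D = 1, DR12 = 1), rate = 2 * kA_E / V),# 5
    reaction(c(DA = 1, DR2 = 1), c(D = 1, DR2 = 1), rate = kA_E / V),      # 6
    reaction(c(D = 1), c(DR1 = 1), rate = k1_W0 + k1_W),                   # 7
    reaction(c(DR1 = 1), c(D = 1), rate = delta_T),                        # 23
    reaction(c(DR1 = 1, DA = 1), c(D = 1, DA = 1), rate = k_TT / V),       # 24
    reaction(c(D = 1), c(DR2 = 1), rate = k2_W0 + k2_W),                   # 8
    reaction(c(DR2 = 1), c(D = 1), rate = delta_R),                        # 21
    reaction(c(DR2 = 1, DA = 1), c(D = 1, DA = 1), rate = kR_E / V),       # 22
    reaction(c(DR1 = 1), c(DR12 = 1), rate = k2_W0),                       # 10
    reaction(c(DR12 = 1), c(DR1 = 1), rate = delta_R),                     # 27
    reaction(c(DR12 = 1, DA = 1), c(DR1 = 1, DA = 1), rate = kR_E / V),    # 28
    reaction(c(DR2 = 1), c(DR12 = 1), rate = k1_W0),                       # 9
    reaction(c(DR12 = 1), c(DR2 = 1), rate = delta_T),                     # 25
    reaction(c(DR12 = 1, DA = 1), c(DR2 = 1, DA = 1), rate = k_TT / V),    # 26
    reaction(c(D = 1, DR2 = 1), c(DR2 = 2), rate = k_M / V),               # 11
    reaction(c(D = 1, DR12 = 1), c(DR2 = 1, DR12 = 1),
             rate = (k_M + kbar_M) / V),                                   # 12
    reaction(c(DR1 = 1, DR2 = 1), c(DR12 = 1, DR2 = 1), rate = k_M / V),   # 13
    reaction(c(DR1 = 1, DR12 = 1), c(DR12 = 2), rate = (k_M + kbar_M) / V),# 14
    reaction(c(D = 1, DR2 = 1), c(DR1 = 1, DR2 = 1), rate = kp_M / V),     # 15
    reaction(c(D = 1, DR12 = 1), c(DR1 = 1, DR12 = 1), rate = kp_M / V),   # 16
    reaction(c(D = 1, DR1 = 1), c(DR2 = 1, DR1 = 1), rate = kbar_M / V),   # 17
    reaction(c(DR2 = 2), c(DR12 = 1, DR2 = 1), rate = kp_M / (2 * V)),     # 18
    reaction(c(DR2 = 1, DR12 = 1), c(DR12 = 2), rate = kp_M / V),          # 19
    reaction(c(DR1 = 2), c(DR12 = 1, DR1 = 1), rate = kbar_M / (2 * V))    # 20
  )
  reaction_network(
    species = c("DR12", "DA", "DR1", "DR2", "D"),
    reactions = rx,
    initial_state = c(DR12 = 0, DA = 0, DR1 = 0, DR2 = 0, D = d_tot)
  )
}

#' Bi-parallel network motif
#'
#' `J -> Y -> W` and `J -> Z -> W`: two parallel conversion pathways between
#' a source and a sink species.  Species order (Y, Z, W, J).
#'
#' @param k1,k2,k3,k4 positive rate constants of the four conversions.
#' @param s_tot conserved total (initially all J).
#' @return a [reaction_network()].
#' @export
scrn_biparallel <- function(k1 = 1, k2 = 1, k3 = 1, k4 = 1, s_tot = 2) {
  reaction_network(
    species = c("Y", "Z", "W", "J"),
    reactions = list(
      reaction(c(J = 1), c(Y = 1), rate = k1),
      reaction(c(J = 1), c(Z = 1), rate = k2),
      reaction(c(Y = 1), c(W = 1), rate = k3),
      reaction(c(Z = 1), c(W = 1), rate = k4)
    ),
    initial_state = c(Y = 0, Z = 0, W = 0, J = s_tot)
  )
}

#' Seeded random unit-transfer network
#'
#' Draws a random digraph on `d` species (optionally bipartite by
#' construction: a random 2-coloring with both classes non-empty and edges
#' only across classes), one mass-action conversion reaction per edge with a
#' log-uniform rate constant in [0.1, 10].  Every vertex is guaranteed at
#' least one incident edge.  Deterministic given `seed`.
#'
#' @param d number of species (>= 2).
#' @param density probability of including each candidate edge.
#' @param bipartite force a bipartite species graph.
#' @param seed integer seed.
#' @param totals optional named/unnamed initial copy numbers; default puts
#'   `tot_per_species` molecules on the first species of each component.
#' @param tot_per_species default total per weakly connected component.
#' @return a [reaction_network()].
#' @export
random_unit_transfer <- function(d = 4, density = 0.4, bipartite = TRUE,
                                 seed = 1, totals = NULL,
                                 tot_per_species = 2) {
  stopifnot(d >= 2)
  set.seed(seed)
  species <- paste0("S", seq_len(d))
  repeat {
    if (bipartite) {
      colouring <- sample(c(1, 2), d, replace = TRUE)
      if (length(unique(colouring)) < 2) next
      cand <- which(outer(colouring, colouring, "!="), arr.ind = TRUE)
    } else {
      cand <- which(outer(seq_len(d), seq_len(d), "!="), arr.ind = TRUE)
    }
    pick <- stats::runif(nrow(cand)) < density
    edges <- cand[pick, , drop = FALSE]
    # cover every vertex with at least one edge
    uncovered <- setdiff(seq_len(d), unique(as.vector(edges)))
    for (v in uncovered) {
      opts <- cand[cand[, 1] == v | cand[, 2] == v, , drop = FALSE]
      if (!nrow(opts)) break
      edges <- rbind(edges, opts[sample.int(nrow(opts), 1), , drop = FALSE])
    }
    if (length(setdiff(seq_len(d), unique(as.vector(edges)))) == 0 &&
        nrow(edges) > 0) break
  }
  edges <- unique(edges)
  rates <- 10^stats::runif(nrow(edges), -1, 1)
  rxs <- lapply(seq_len(nrow(edges)), function(i) {
    r <- stats::setNames(1, species[edges[i, 1]])
    p <- stats::setNames(1, species[edges[i, 2]])
    reaction(r, p, rate = rates[i])
  })
  net <- reaction_network(species, rxs)
  g <- species_graph(net)
  if (is.null(totals)) {
    init <- stats::setNames(numeric(d), species)
    for (q in seq_len(g$n_components)) {
      members <- which(g$component == q)
      init[members[1]] <- tot_per_species
    }
  } else {
    init <- totals
  }
  reaction_network(species, rxs, initial_state = init)
}
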
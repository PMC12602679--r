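# enumerate {x in Z_+^m : sum(x) <= tot} in lexicographic order
.simplex_states <- function(m, tot) {
  if (m == 0) return(matrix(numeric(0), nrow = 1, ncol = 0))
  out <- matrix(0, nrow = 0, ncol = m)
  rec <- function(prefix, remaining) {
    if (length(prefix) == m) {
      out <<- rbind(out, prefix)
      return(invisible())
    }
    for (v in 0:remaining) rec(c(prefix, v), remaining - v)
  }
  rec(numeric(0), tot)
  rownames(out) <- NULL
  out
}

#' Enumerate the projected state space on the conservation simplex
#'
#' For each multi-vertex weakly connected component the projected coordinates
#' (component species minus the last) range over the simplex
#' `{x >= 0 : sum(x) <= x_tot}` with the component's conserved total; the
#' full space is the product over components, in deterministic lexicographic
#' order.  Singleton components carry a constant copy number and contribute
#' no coordinate.
#'
#' @param net a unit-transfer [reaction_network()].
#' @param initial_state named non-negative integer vector over all species
#'   (defaults to `net$initial_state`); defines per-component totals.
#' @return object of class `projected_state_space` with `states` (N x (d-p)
#'   matrix, columns named by projected species), `totals` (per component),
#'   `info` (projection bookkeeping), and `index` lookup.
#' @export
projected_state_space <- function(net, initial_state = net$initial_state) {
  if (is.null(initial_state))
    stop("an initial state (or conserved totals) is required")
  g <- species_graph(net)
  info <- projection_info(net, g)
  initial_state <- initial_state[net$species]
  if (any(is.na(initial_state)))
    stop("initial_state must cover every species")
  totals <- vapply(seq_len(g$n_components), function(q)
    sum(initial_state[which(g$component == q)]), numeric(1))

  per_comp <- lapply(seq_len(g$n_components), function(q) {
    m <- length(info$coord_of[[q]])
    .simplex_states(m, totals[q])
  })
  states <- matrix(numeric(0), nrow = 1, ncol = 0)
  for (q in seq_len(g$n_components)) {
    sq <- per_comp[[q]]
    if (ncol(sq) == 0) next
    states <- cbind(states[rep(seq_len(nrow(states)), each = nrow(sq)), ,
                           drop = FALSE],
                    sq[rep(seq_len(nrow(sq)), times = max(1, nrow(states))), ,
                       drop = FALSE])
  }
  if (ncol(states) == 0 || nrow(states) <= 1)
    stop("degenerate projected state space (fewer than two states)")
  colnames(states) <- info$coord_species
  keys <- apply(states, 1, paste, collapse = ",")
  structure(list(states = states, totals = totals, info = info,
                 keys = keys, net = net),
            class = "projected_state_space")
}

#' @export
print.projected_state_space <- function(x, ...) {
  cat("<projected_state_space> ", nrow(x$states), " states in dimension ",
      ncol(x$states), "; totals: ", paste(x$totals, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# lift a projected state (row vector on coord_species) to the full state in
# original species order
.lift_state <- function(space, xhat) {
  info <- space$info
  g <- info$graph
  full <- numeric(length(space$net$species))
  for (q in seq_along(info$coord_of)) {
    members <- which(g$component == q)
    coords <- info$coord_of[[q]]
    if (length(coords)) {
      vals <- xhat[coords]
      lastval <- space$totals[q] - sum(vals)
      if (lastval < 0)
        stop("lift error: negative reconstructed copy number ",
             "(inconsistent totals)")
      full[members] <- c(vals, lastval)
    } else {
      full[members] <- space$totals[q]
    }
  }
  names(full) <- space$net$species
  full
}

#' Build the sparse generator of the projected chain
#'
#' The rate from `x` to `x + v_k` (projected) is the total mass-action
#' propensity of the vector-k reaction group evaluated at the lifted full
#' state; transitions leaving the simplex get rate 0; the diagonal makes
#' rows sum to zero.
#'
#' @param net a unit-transfer [reaction_network()].
#' @param space a [projected_state_space()].
#' @return object of class `projected_generator` with `Q` (sparse dgCMatrix),
#'   and `moves` (per reaction vector: from-index, to-index, rate triples).
#' @export
projected_generator <- function(net, space) {
  stopifnot(inherits(space, "projected_state_space"))
  info <- space$info
  N <- nrow(space$states)
  n <- ncol(net$V)
  moves <- vector("list", n)
  ii <- jj <- vv <- numeric(0)
  for (k in seq_len(n)) {
    vk <- info$vcheck[, k]
    from <- to <- rate <- numeric(0)
    for (s in seq_len(N)) {
      target <- space$states[s, ] + vk
      key <- paste(target, collapse = ",")
      t_idx <- match(key, space$keys)
      if (is.na(t_idx)) next
      full <- .lift_state(space, space$states[s, ])
      r <- total_propensity(net, k, full)
      if (r <= 0) next
      from <- c(from, s); to <- c(to, t_idx); rate <- c(rate, r)
    }
    moves[[k]] <- cbind(from = from, to = to, rate = rate)
    ii <- c(ii, from); jj <- c(jj, to); vv <- c(vv, rate)
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  Q <- Q - Matrix::Diagonal(x = Matrix::rowSums(Q))
  structure(list(Q = Q, moves = moves, space = space),
            class = "projected_generator")
}

#' Decompose the state space into level sets
#'
#' Computes `z = b' x` for every state, checks the coclique property (no
#' positive rate between two states of the same level) and that no
#' intermediate level set between the extremes is empty.
#'
#' @param L a `coclique_level_function` (on the full projected coordinates).
#' @param space a [projected_state_space()].
#' @param gen a [projected_generator()].
#' @return object of class `level_decomposition` with `level_of` (per state),
#'   `levels` (l..u), `sets` (list of state-index vectors), `l`, `u`.
#' @export
level_decomposition <- function(L, space, gen) {
  stopifnot(inherits(L, "coclique_level_function"))
  if (length(L$b) != ncol(space$states))
    stop("level function dimension does not match the state space")
  z <- as.numeric(space$states %*% L$b)
  l <- min(z); u <- max(z)
  sets <- lapply(l:u, function(zz) which(z == zz))
  names(sets) <- as.character(l:u)
  empty <- which(vapply(sets, length, integer(1)) == 0)
  if (length(empty))
    stop("empty intermediate level set(s) at z = ",
         paste((l:u)[empty], collapse = ", "),
         "; birth-death bounds are undefined")
  # coclique check: every positive transition changes the level by exactly 1
  for (k in seq_along(gen$moves)) {
    mv <- gen$moves[[k]]
    if (!nrow(mv)) next
    dz <- z[mv[, "to"]] - z[mv[, "from"]]
    if (any(abs(dz) != 1))
      stop("not a coclique level function for this chain: transition with ",
           "level change ", paste(unique(dz[abs(dz) != 1]), collapse = ","))
  }
  structure(list(level_of = z, levels = l:u, sets = sets, l = l, u = u),
            class = "level_decomposition")
}

#' Per-level transition-rate extrema
#'
#' Splits the reaction vectors into `G+` (level +1) and `G-` (level -1) using
#' the signs of the level function, computes the per-state rates of increase
#' and decrease, and takes per-level maxima/minima.  Also checks the standing
#' assumption behind the bounding chains: every state off the top level has a
#' feasible up-move when `G+` is non-empty (and mirrored for `G-`).
#'
#' @param L a `coclique_level_function`.
#' @param space a [projected_state_space()].
#' @param gen a [projected_generator()].
#' @param decomp optional precomputed [level_decomposition()].
#' @return object of class `level_rate_summary` with per-level `lambda_max`,
#'   `lambda_min`, `gamma_max`, `gamma_min` (named by level), per-state
#'   `lambda`, `gamma`, the sets `G_plus`, `G_minus`, and per-state feasible
#'   move sets.
#' @export
level_rate_summary <- function(L, space, gen,
                               decomp = level_decomposition(L, space, gen)) {
  n <- length(L$signs)
  G_plus <- which(L$signs == 1)
  G_minus <- which(L$signs == -1)
  N <- nrow(space$states)
  lambda <- gamma <- numeric(N)
  feas_plus <- feas_minus <- vector("list", N)
  rate_of <- function(k) {
    out <- numeric(N)
    mv <- gen$moves[[k]]
    if (nrow(mv)) out[mv[, "from"]] <- mv[, "rate"]
    out
  }
  feasible_of <- function(k) {
    # feasible = target inside the state space (rate may still be 0)
    vk <- space$info$vcheck[, k]
    vapply(seq_len(N), function(s)
      !is.na(match(paste(space$states[s, ] + vk, collapse = ","),
                   space$keys)), logical(1))
  }
  fp <- matrix(FALSE, N, n);
  for (k in seq_len(n)) fp[, k] <- feasible_of(k)
  for (k in G_plus) lambda <- lambda + rate_of(k)
  for (k in G_minus) gamma <- gamma + rate_of(k)
  for (s in seq_len(N)) {
    feas_plus[[s]] <- G_plus[fp[s, G_plus]]
    feas_minus[[s]] <- G_minus[fp[s, G_minus]]
  }
  z <- decomp$level_of
  top <- decomp$sets[[as.character(decomp$u)]]
  bottom <- decomp$sets[[as.character(decomp$l)]]
  if (length(G_plus)) {
    off_top <- setdiff(seq_len(N), top)
    if (any(vapply(feas_plus[off_top], length, integer(1)) == 0))
      stop("standing assumption violated: a state off the top level has no ",
           "feasible up-move")
  }
  if (length(G_minus)) {
    off_bottom <- setdiff(seq_len(N), bottom)
    if (any(vapply(feas_minus[off_bottom], length, integer(1)) == 0))
      stop("standing assumption violated: a state off the bottom level has ",
           "no feasible down-move")
  }
  levels <- decomp$levels
  stat <- function(fun, vals) vapply(levels, function(zz)
    fun(vals[decomp$sets[[as.character(zz)]]]), numeric(1))
  out <- list(lambda_max = stat(max, lambda), lambda_min = stat(min, lambda),
              gamma_max = stat(max, gamma), gamma_min = stat(min, gamma),
              lambda = lambda, gamma = gamma,
              G_plus = G_plus, G_minus = G_minus,
              feas_plus = feas_plus, feas_minus = feas_minus,
              decomp = decomp, space = space)
  for (nm in c("lambda_max", "lambda_min", "gamma_max", "gamma_min"))
    names(out[[nm]]) <- as.character(levels)
  structure(out, class = "level_rate_summary")
}

#' Bounding generators
#'
#' Builds the two comparison generators: the fast chain splits the per-level
#' maximal up-rate equally over feasible up-moves and the minimal down-rate
#' over feasible down-moves; the slow chain mirrors with minimal up-rates and
#' maximal down-rates.  The level process of each is a birth-death chain.
#'
#' @param summary a [level_rate_summary()].
#' @return list with sparse generators `Q_fast` and `Q_slow`.
#' @export
bounding_generators <- function(summary) {
  stopifnot(inherits(summary, "level_rate_summary"))
  space <- summary$space
  decomp <- summary$decomp
  N <- nrow(space$states)
  build <- function(up_rates, down_rates) {
    ii <- jj <- vv <- numeric(0)
    for (s in seq_len(N)) {
      z <- as.character(decomp$level_of[s])
      fp <- summary$feas_plus[[s]]
      fm <- summary$feas_minus[[s]]
      if (length(fp) && up_rates[[z]] > 0) {
        for (k in fp) {
          t_idx <- match(paste(space$states[s, ] + space$info$vcheck[, k],
                               collapse = ","), space$keys)
          ii <- c(ii, s); jj <- c(jj, t_idx)
          vv <- c(vv, up_rates[[z]] / length(fp))
        }
      }
      if (length(fm) && down_rates[[z]] > 0) {
        for (k in fm) {
          t_idx <- match(paste(space$states[s, ] + space$info$vcheck[, k],
                               collapse = ","), space$keys)
          ii <- c(ii, s); jj <- c(jj, t_idx)
          vv <- c(vv, down_rates[[z]] / length(fm))
        }
      }
    }
    Q <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
    Q <- Q - Matrix::Diagonal(x = Matrix::rowSums(Q))
    Q
  }
  list(Q_fast = build(summary$lambda_max, summary$gamma_min),
       Q_slow = build(summary$lambda_min, summary$gamma_max))
}
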
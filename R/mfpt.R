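#' Birth-death chain specification
#'
#' Levels run `l..u`; `up_rates[z]` is the rate from level z to z+1 for
#' `z = l..u-1`, `down_rates[z]` the rate from z to z-1 for `z = l+1..u`.
#'
#' @param l,u integer level range, `l < u`.
#' @param up_rates numeric vector of length `u - l` (levels l..u-1).
#' @param down_rates numeric vector of length `u - l` (levels l+1..u).
#' @return object of class `birth_death_spec`.
#' @export
birth_death_spec <- function(l, u, up_rates, down_rates) {
  stopifnot(u > l, length(up_rates) == u - l, length(down_rates) == u - l,
            all(is.finite(up_rates)), all(is.finite(down_rates)),
            all(up_rates >= 0), all(down_rates >= 0))
  structure(list(l = l, u = u, up_rates = as.numeric(up_rates),
                 down_rates = as.numeric(down_rates)),
            class = "birth_death_spec")
}

#' Reflect a birth-death spec
#'
#' The relabeling `z -> l + u - z` swaps the roles of up- and down-moves:
#' the reflected chain's up-rate at level z equals the original down-rate at
#' `l + u - z` and vice versa.
#'
#' @param spec a [birth_death_spec()].
#' @return the reflected [birth_death_spec()].
#' @export
reflect_spec <- function(spec) {
  stopifnot(inherits(spec, "birth_death_spec"))
  birth_death_spec(spec$l, spec$u,
                   up_rates = rev(spec$down_rates),
                   down_rates = rev(spec$up_rates))
}

#' Mean first passage time of a birth-death chain from bottom to top
#'
#' Closed form for the expected hitting time of level u starting from level
#' l: \deqn{h_{l,u} = \frac{1}{\lambda_{u-1}} + \sum_{i=l}^{u-2}
#' \frac{1}{\lambda_i}\Big(1 + \sum_{j=i+1}^{u-1}
#' \frac{\gamma_{i+1}\cdots\gamma_j}{\lambda_{i+1}\cdots\lambda_j}\Big)}
#' evaluated with cumulative products in O((u-l)^2).  Requires every up-rate
#' positive.
#'
#' @param spec a [birth_death_spec()].
#' @return the mean first passage time (finite positive number).
#' @export
birth_death_mfpt_up <- function(spec) {
  stopifnot(inherits(spec, "birth_death_spec"))
  lam <- spec$up_rates                  # levels l .. u-1
  gam <- spec$down_rates                # levels l+1 .. u
  m <- length(lam)
  if (any(lam <= 0))
    stop("up-rate zero at level ", spec$l + which(lam <= 0)[1] - 1,
         "; the bottom-to-top passage time is undefined (infinite)")
  # ratio[j] = gamma_{l+j} / lambda_{l+j} for j = 1..m-1
  total <- 1 / lam[m]
  if (m >= 2) {
    for (i in seq_len(m - 1)) {           # i-th term: level l + i - 1
      acc <- 1
      s <- 1
      for (j in i:(m - 1)) {              # product up to level l + j
        acc <- acc * gam[j] / lam[j + 1]
        s <- s + acc
      }
      total <- total + s / lam[i]
    }
  }
  total
}

#' Mean first passage time of a birth-death chain from top to bottom
#'
#' Obtained from [birth_death_mfpt_up()] by the level reflection
#' `z -> l + u - z`, which swaps up- and down-rates.  Requires every
#' down-rate positive.
#'
#' @param spec a [birth_death_spec()].
#' @return the mean first passage time.
#' @export
birth_death_mfpt_down <- function(spec) {
  stopifnot(inherits(spec, "birth_death_spec"))
  if (any(spec$down_rates <= 0))
    stop("down-rate zero at level ",
         spec$l + which(spec$down_rates <= 0)[1],
         "; the top-to-bottom passage time is undefined (infinite)")
  birth_death_mfpt_up(reflect_spec(spec))
}

#' Four closed-form MFPT bounds from a level-rate summary
#'
#' The comparison chains give, for the passage from the bottom level set to
#' the top, a lower bound from the fast chain (per-level maximal up-rates,
#' minimal down-rates) and an upper bound from the slow chain (minimal
#' up-rates, maximal down-rates); for the top-to-bottom passage the roles
#' swap.  Each direction has its own positivity precondition; a direction
#' whose precondition fails is reported as undefined rather than failing the
#' whole computation.
#'
#' @param summary a [level_rate_summary()].
#' @return object of class `mfpt_bound_report` with `lower_up`, `upper_up`,
#'   `lower_down`, `upper_down` (NA when undefined, with the reason in
#'   `notes`), the level range, and the level function's coefficients.
#' @export
mfpt_bounds <- function(summary) {
  stopifnot(inherits(summary, "level_rate_summary"))
  d <- summary$decomp
  l <- d$l; u <- d$u
  zl <- as.character(l:(u - 1))     # up-rate levels
  zu <- as.character((l + 1):u)     # down-rate levels
  spec_fast <- birth_death_spec(l, u, summary$lambda_max[zl],
                                summary$gamma_min[zu])
  spec_slow <- birth_death_spec(l, u, summary$lambda_min[zl],
                                summary$gamma_max[zu])
  res <- list(lower_up = NA_real_, upper_up = NA_real_,
              lower_down = NA_real_, upper_down = NA_real_)
  notes <- character(0)
  try_bound <- function(f, spec, what) {
    tryCatch(f(spec), error = function(e) {
      notes <<- c(notes, paste0(what, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  res$lower_up <- try_bound(birth_death_mfpt_up, spec_fast, "lower_up")
  res$upper_up <- try_bound(birth_death_mfpt_up, spec_slow, "upper_up")
  res$lower_down <- try_bound(birth_death_mfpt_down, spec_slow, "lower_down")
  res$upper_down <- try_bound(birth_death_mfpt_down, spec_fast, "upper_down")
  structure(c(res, list(l = l, u = u, notes = notes,
                        spec_fast = spec_fast, spec_slow = spec_slow)),
            class = "mfpt_bound_report")
}

#' @export
print.mfpt_bound_report <- function(x, ...) {
  cat("<mfpt_bound_report> levels ", x$l, "..", x$u, "\n", sep = "")
  cat(sprintf("  bottom -> top: [%g, %g]\n", x$lower_up, x$upper_up))
  cat(sprintf("  top -> bottom: [%g, %g]\n", x$lower_down, x$upper_down))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Exact mean first passage time by sparse linear solve
#'
#' First-step analysis: restricting the generator to non-target states, the
#' vector of expected hitting times solves `Q_rr h = -1` with `h = 0` on the
#' target.  A singular restricted generator means the target is unreachable
#' from some state.
#'
#' @param Q generator matrix (dense or sparse) over an enumerated state space.
#' @param target integer indices of the target set.
#' @param start integer index (or indices) of the start state(s).
#' @return expected hitting time(s) from `start`, as a numeric vector.
#' @export
exact_mfpt <- function(Q, target, start) {
  N <- nrow(Q)
  if (!length(target) || length(target) >= N)
    stop("target must be a nonempty proper subset of the state space")
  if (any(start < 1 | start > N)) stop("start state outside the state space")
  rest <- setdiff(seq_len(N), target)
  Qrr <- Q[rest, rest, drop = FALSE]
  h <- tryCatch(
    Matrix::solve(Qrr, rep(-1, length(rest))),
    error = function(e)
      stop("restricted generator is singular: target unreachable from some ",
           "state (", conditionMessage(e), ")")
  )
  h <- as.numeric(h)
  if (any(!is.finite(h)) || any(h < -1e-9))
    stop("non-finite or negative hitting times: target unreachable")
  full <- numeric(N)
  full[rest] <- h
  full[start]
}

#' Cascade MFPT via the hypoexponential closed form
#'
#' For the three-species conversion cascade with rates `alpha` then `beta`,
#' each of the `n_tot` molecules independently takes a hypoexponential
#' (sum-of-two-exponentials) time to convert; the passage time to the fully
#' converted state is the maximum, with mean
#' \deqn{\int_0^\infty (1 - F(x)^{n_{tot}})\,dx,}
#' where F is the hypoexponential CDF (Erlang-2 when `alpha == beta`).
#'
#' @param alpha,beta positive conversion rates.
#' @param n_tot number of molecules (>= 1).
#' @param rel_tol relative tolerance of the quadrature.
#' @return the mean first passage time.
#' @export
cascade_hypoexp_mfpt <- function(alpha, beta, n_tot, rel_tol = 1e-9) {
  stopifnot(alpha > 0, beta > 0, n_tot >= 1)
  Fx <- if (alpha == beta) {
    function(x) 1 - exp(-alpha * x) * (1 + alpha * x)
  } else {
    function(x) 1 - (beta * exp(-alpha * x) - alpha * exp(-beta * x)) /
      (beta - alpha)
  }
  integrand <- function(x) 1 - Fx(x)^n_tot
  stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                   subdivisions = 1000L)$value
}

#' Log-log scaling exponent
#'
#' Least-squares slope of `log(value)` against `log(1/eps)` over a geometric
#' grid, used to read off asymptotic orders such as O(1/eps).
#'
#' @param eps numeric vector (>= 4 points, positive, geometric grid).
#' @param values positive numeric vector of the same length.
#' @return list with `slope` and `r_squared`.
#' @export
scaling_exponent <- function(eps, values) {
  stopifnot(length(eps) >= 4, length(values) == length(eps),
            all(eps > 0), all(is.finite(values)))
  if (any(values <= 0)) stop("values must be positive for log-log fitting")
  fit <- stats::lm(log(values) ~ log(1 / eps))
  y <- log(values)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}
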
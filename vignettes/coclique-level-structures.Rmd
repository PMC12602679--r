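---
title: "Coclique level structures and passage-time bounds for unit-transfer reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coclique level structures and passage-time bounds for unit-transfer reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coclique)
```

## The model

A stochastic chemical reaction network (SCRN) is a continuous-time Markov
chain $X$ on copy-number vectors $x \in \mathbb{Z}_+^d$ of $d$ species, whose
transitions are reactions.  Under mass-action kinetics a reaction with
reactant counts $v^-$, product counts $v^+$ and rate constant $\kappa$ fires
at propensity $\kappa \prod_i (x_i)_{(v^-)_i}$, with $(m)_\ell$ the falling
factorial; the net change is the reaction vector $v = v^+ - v^-$.  The
distinct reaction vectors form the columns of the stoichiometric matrix $S$,
and any $m \neq 0$ with $m^T S = 0$ is a conservation vector: $m^T X(t)$ is
constant, so the chain can be projected onto fewer coordinates.

This package handles **unit-transfer** networks: every reaction vector has a
single $+1$, a single $-1$ and zeros elsewhere, i.e. each reaction converts
one molecule of one species into one molecule of another (possibly in the
presence of catalysts, which appear on both sides).  For such networks the
species digraph $\mathcal{G}$ — one vertex per species, one edge
$e_k = (i, j)$ per reaction vector with $v_k(i) = -1$, $v_k(j) = +1$ —
carries all the structure that matters:

* each weakly connected component of $\mathcal{G}$ conserves its total copy
  number, so $\mathrm{rank}(S) = d - p$ with $p$ components, and the
  deficiency $d - p - \mathrm{rank}(S)$ is always zero;
* the projected chain $\check X$ drops the last species of each component
  and lives on a product of integer simplices
  $\{\check x \ge 0 : \sum_i \check x^q_i \le x^q_{\mathrm{tot}}\}$.

A **coclique level function** is an integer-linear $L(\check x) = b^T \check
x$ with $L(\check v_k) \in \{-1, +1\}$ for every projected reaction vector.
Its level sets $\mathcal{L}_z = \{\check x : L(\check x) = z\}$,
$z = \ell, \dots, u$, partition the state space into cocliques — no direct
transition stays inside a level — so the image process $L(\check X)$ moves
between adjacent levels only.  That one-dimensional skeleton is what makes
closed-form passage-time bounds possible.

## Enumerating all level functions

Fixing which edges increase $L$ and which decrease it (an edge partition
$\{\mathcal{E}_+, \mathcal{E}_-\}$) turns the defining condition into the
linear system $\check S^T b = w$ with $w_k = \pm 1$.  On a weakly connected
component this system has full column rank, hence zero or one solution, and
any solution is integral.  The enumeration therefore:

1. tests each component for bipartiteness (a non-bipartite component has an
   odd cycle, which obstructs every partition, so no level function exists);
2. keeps one member of each antiparallel vector pair (the partner's equation
   is the negation of its mate's, so the pair must take opposite signs);
3. iterates the $2^{|\hat{\mathcal{V}}|-1}$ sign assignments over the reduced
   vector set with the first vector's sign fixed at $+1$ (identifying $L$
   with $-L$), optionally pruning assignments whose signed sum around some
   basis cycle is nonzero, and solves each remaining system exactly;
4. composes per-component solutions into functions on the full projected
   space by signed sums over multi-vertex components, deduplicated under
   global negation.

Exactness matters here: ranks, null spaces and the partition systems are
solved over the rationals (a small internal fraction-arithmetic
elimination), never in floating point, because the integrality of solutions
and the zero/one solution dichotomy are exact statements.  Numerators stay
tiny for the intended network sizes ($d \lesssim 15$), so double-held
integers are exact.

Conventions chosen where any would do, fixed for reproducibility:

* species order is the declared order; components are relabelled
  contiguously by smallest member index; the dropped species is the last of
  each component;
* two-colorings come from BFS at the lowest-index vertex, root in class B;
* output order is lexicographic over sign assignments ($+1$ before $-1$);
  each function is canonicalized so its first nonzero coefficient is
  positive;
* the cycle-obstruction certificate is only a fast path — the exact solver
  decides, and the test suite checks the two agree on every sign vector of
  small networks.

The enumeration is exponential in the reduced vector count by design; no
heuristics are layered on top, and a brute-force enumeration over all $2^n$
partitions is kept in the test suite as an oracle for $n \le 8$.

## Birth–death comparison bounds for mean first passage times

Write $G_+ = \{k : L(\check v_k) = 1\}$ and $G_- = \{k : L(\check v_k) =
-1\}$, and for a state at level $z$ define its rate of increase
$\lambda_z(\check x)$ (sum of outgoing rates over $G_+$) and rate of
decrease $\gamma_z(\check x)$.  Per level, take the extrema
$\lambda^M_z, \lambda^m_z, \gamma^M_z, \gamma^m_z$.  Two comparison chains
on the same state space redistribute these extremal rates uniformly over
the feasible moves of each state: the *fast* chain uses
$(\lambda^M_z, \gamma^m_z)$ and the *slow* chain $(\lambda^m_z,
\gamma^M_z)$.  Their level processes are genuine birth–death chains, and
coupling arguments give, for starts in $\mathcal{L}_\ell$,

$$\breve h_{\ell,u} \;\le\; \mathbb{E}[\tau_u] \;\le\; \overset{\frown}{h}_{\ell,u},$$

and symmetrically for the passage from $\mathcal{L}_u$ down to
$\mathcal{L}_\ell$ (there the fast chain gives the *upper* bound).  The
birth–death expected hitting time from $\ell$ to $u$ is evaluated in
closed form,

$$h_{\ell,u} = \frac{1}{\lambda_{u-1}} + \sum_{i=\ell}^{u-2}
  \frac{1}{\lambda_i}\Big(1 + \sum_{j=i+1}^{u-1}
  \frac{\gamma_{i+1}\cdots\gamma_j}{\lambda_{i+1}\cdots\lambda_j}\Big),$$

with cumulative products ($O((u-\ell)^2)$), and the downward time by the
reflection $z \mapsto \ell + u - z$ that swaps up- and down-rates.  The
reflection identity is exposed as `reflect_spec()` so it can be (and is)
falsified against dense first-step solves of the same chains.  Each
direction has its own positivity precondition (all relevant up-rates,
respectively down-rates, positive); a failing direction is reported as
undefined rather than aborting the other one.

Two degeneracies are treated as hard errors with diagnostics rather than
silently skipped, because the extremal rates would be taken over empty sets:
an empty intermediate level set, and a state off the extreme levels with no
feasible move in the required direction (the standing assumption behind the
uniform redistribution).

Exact MFPTs for validation come from first-step analysis: restrict the
sparse generator to non-target states and solve $\check Q_{rr} h = -1$
(direct sparse factorization; the state spaces targeted here are at most a
few thousand states).  A singular restricted system is reported as an
unreachable target — for irreversible chains one direction is genuinely
infinite and the report says so.

## Example networks and the synthetic generator

The package ships constructors for the networks used throughout the test
suite: a three-species conversion cascade (`scrn_cascade()`), a pair of
independent subsystems and a catalytically coupled variant
(`scrn_two_component()`, `scrn_coupled()`), a histone-modification circuit
(`scrn_histone()`), a full chromatin circuit with DNA methylation
(`scrn_full_chromatin()`), and a bi-parallel conversion motif
(`scrn_biparallel()`).  The chromatin circuits take dimensionless ratios —
$\varepsilon$ (basal erasure over autocatalytic establishment), $\mu$,
$\tilde b$, $\mu'$, $\beta$ — and derive the raw constants through the
identities $\delta_A = \varepsilon k^A_M D_{tot}/V$,
$\delta_R = \delta_A \mu \tilde b$, $k^R_E = \mu k^A_E$,
$k^{\prime*}_T = \mu' k^A_E$, $\delta' + k'_T = \beta \mu' \delta_A$.
Base constants default to 1 and $V = 1$; every test states its own
parameters.  Bimolecular constants are folded as $\kappa/V$ and homodimeric
ones as $\kappa/(2V)$, so the falling-factorial propensity
$\frac{\kappa}{2V} x (x-1)$ reproduces the conventional
$\kappa x(x-1)/(2V)$ rate; the test suite checks every constructor's
generator symbolically against the intended rate functions at random
states.

`random_unit_transfer()` draws seeded random unit-transfer networks — a
random digraph (optionally bipartite by construction via a random
2-coloring), one conversion reaction per edge, log-uniform constants in
$[0.1, 10]$ — for property tests: deficiency zero always; existence of a
level function if and only if every multi-vertex component is bipartite;
reduced enumeration equal to brute force; bound sandwiches against exact
solves.  These networks emulate the combinatorial variety of small
conversion networks, not the kinetic realism of any particular biological
system: rate constants are independent and there is no volume scaling, so
passing the property suite says nothing about fit to real kinetic data —
only that the structural theory and the bound algebra are implemented
correctly.

Problem sizes in the test suite are deliberate: conserved totals up to 4 on
the example networks, random networks with $d \le 6$ and totals up to 3,
100 random instances per property.  These sizes already exercise every
code path (multi-component spaces, empty-direction degeneracies,
unreachable targets) while keeping the exact-solve oracles instantaneous.

## Scaling diagnostics and a known discrepancy

For the chromatin circuits the interesting question is how the bounds grow
as $\varepsilon \to 0$.  `scaling_exponent()` fits the log-log slope of a
bound against $1/\varepsilon$ on a geometric grid.  For the histone circuit
all four bounds grow like $\varepsilon^{-1}$ (measured slopes within 0.01
of 1 on $\varepsilon \in [10^{-5}, 10^{-2}]$).  For the full chromatin
circuit the top-to-bottom *lower* bound grows like $\varepsilon^{-2}$.
The top-to-bottom *upper* bound, however, grows like
$\varepsilon^{-(D_{tot}+1)}$, not $\varepsilon^{-D_{tot}}$ as sometimes
stated for this circuit: the band of levels whose minimal rate of decrease
is $O(\varepsilon)$ is $[D_{tot}, 2D_{tot}]$ — that is $D_{tot}+1$ levels —
and the dominant term of the closed form is
$(1/\gamma^m_u)\prod_{t=D_{tot}}^{u-1}\lambda^M_t/\gamma^m_t$, one
$\varepsilon^{-1}$ factor per band level.  The measured slope at
$D_{tot} = 3$ is $4.0$ with $R^2 \approx 1$, confirming the count.  The
bound is of course still a valid upper bound; it is simply looser than the
$\varepsilon^{-2}$ growth of the exact passage time.

## Limitations

* Only finite simplex-product state spaces: a conserved total per component
  is required, and more general truncated spaces are supported only through
  the automatic rule that propensities vanish on moves leaving the simplex.
* Enumeration cost is $2^{|\hat{\mathcal{V}}|-1}$ exact solves — fine for
  $d \lesssim 15$, not for genome-scale networks.
* Mass-action propensities only; constants must be pre-scaled for volume.
* Bounds require the feasible-move standing assumption and fully populated
  level ranges; the package errors loudly when either fails rather than
  extrapolating.
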
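test_that("birth-death closed forms match hand-computed and solver values", {
  # pure birth at constant rate c over k levels: k/c
  spec <- birth_death_spec(0, 4, up_rates = rep(2, 4), down_rates = rep(0, 4))
  expect_equal(birth_death_mfpt_up(spec), 2)

  # 3-state chain, unit rates: frozen value from the first-step solve
  spec3 <- birth_death_spec(0, 2, up_rates = c(1, 1), down_rates = c(1, 1))
  expect_equal(birth_death_mfpt_up(spec3), 3)
  expect_equal(birth_death_mfpt_down(spec3), 3)

  # pure death: (u - l)/c
  specd <- birth_death_spec(0, 3, up_rates = c(1, 1, 1),
                            down_rates = rep(4, 3))
  expect_error(birth_death_mfpt_up(
    birth_death_spec(0, 2, c(1, 0), c(1, 1))), "undefined")
  expect_equal(birth_death_mfpt_down(
    birth_death_spec(0, 3, rep(0, 3), rep(4, 3))), 3 / 4)

  # degenerate two-level chain reduces to a single exponential mean
  expect_equal(birth_death_mfpt_up(birth_death_spec(0, 1, 5, 1)), 1 / 5)
  expect_equal(birth_death_mfpt_down(birth_death_spec(0, 1, 5, 3)), 1 / 3)
})

test_that("closed forms agree with exact solves of random birth-death chains", {
  set.seed(42)
  for (rep in 1:50) {
    l <- sample(-3:2, 1)
    u <- l + sample(2:6, 1)
    up <- stats::runif(u - l, 0.1, 5)
    down <- stats::runif(u - l, 0.1, 5)
    spec <- birth_death_spec(l, u, up, down)
    expect_equal(birth_death_mfpt_up(spec),
                 bd_exact_mfpt(l, u, up, down, l, u), tolerance = 1e-9)
    expect_equal(birth_death_mfpt_down(spec),
                 bd_exact_mfpt(l, u, up, down, u, l), tolerance = 1e-9)
    # reflection identity is definitional
    expect_equal(birth_death_mfpt_down(spec),
                 birth_death_mfpt_up(reflect_spec(spec)), tolerance = 1e-12)
  }
})

test_that("bound reports handle direction-specific degeneracy", {
  an <- mfpt_analysis(scrn_cascade(1, 1, 2), c(1, 2))
  expect_true(is.finite(an$bounds$lower_up))
  expect_true(is.finite(an$bounds$upper_up))
  expect_true(is.na(an$bounds$lower_down))      # no rate of decrease
  expect_true(is.na(an$bounds$upper_down))
  expect_true(any(grepl("down", an$bounds$notes)))
  # with no decrease the lower bound collapses to sum of inverse max rates
  summ <- an$summary
  zl <- as.character(an$decomposition$l:(an$decomposition$u - 1))
  expect_equal(an$bounds$lower_up, sum(1 / summ$lambda_max[zl]))

  anh <- mfpt_analysis(scrn_histone(eps = 0.3, d_tot = 2), c(1, -1))
  expect_true(all(is.finite(unlist(anh$bounds[c("lower_up", "upper_up",
                                                "lower_down", "upper_down")]))))
})

test_that("exact MFPTs from the sparse solve match first principles", {
  # N_tot = 1 cascade: sum of two exponential means
  an <- mfpt_analysis(scrn_cascade(2, 5, 1), c(1, 2))
  expect_equal(an$exact_up, 1 / 2 + 1 / 5, tolerance = 1e-12)

  # 2-state chain with rate q: the only reachable direction is downhill
  an2 <- mfpt_analysis(two_species_net(tot = 1), 1)
  expect_equal(an2$exact_down, 1, tolerance = 1e-12)
  expect_true(is.na(an2$exact_up))   # upstream target unreachable

  # symmetric histone parameters make the two directions equal
  anh <- mfpt_analysis(scrn_histone(eps = 0.2, mu = 1, b_tilde = 1,
                                    d_tot = 2), c(1, -1))
  expect_equal(anh$exact_up, anh$exact_down, tolerance = 1e-9)

  # unreachable targets are flagged (downhill-only chain, upstream target)
  net <- scrn_cascade(1, 1, 2)
  sp <- projected_state_space(net)
  gen <- projected_generator(net, sp)
  expect_error(exact_mfpt(gen$Q, target = match("0,0", sp$keys),
                          start = match("0,2", sp$keys)),
               "unreachable|singular")
})

test_that("the hypoexponential integral equals the linear-solve oracle", {
  expect_equal(cascade_hypoexp_mfpt(2, 5, 1), 1 / 2 + 1 / 5,
               tolerance = 1e-8)
  expect_equal(cascade_hypoexp_mfpt(1, 1, 1), 2, tolerance = 1e-8)
  for (ab in list(c(0.5, 2), c(1, 1), c(2, 0.5))) {
    for (n in c(1, 3)) {
      an <- mfpt_analysis(scrn_cascade(ab[1], ab[2], n), c(1, 2),
                          exact = TRUE)
      expect_equal(cascade_hypoexp_mfpt(ab[1], ab[2], n), an$exact_up,
                   tolerance = 1e-6)
    }
  }
  expect_error(cascade_hypoexp_mfpt(-1, 1, 1))
})

test_that("scaling exponents recover exact power laws", {
  eps <- 10^-(2:5)
  expect_equal(scaling_exponent(eps, 3 / eps)$slope, 1, tolerance = 1e-9)
  expect_equal(scaling_exponent(eps, 0.5 / eps^2)$slope, 2, tolerance = 1e-9)
  expect_error(scaling_exponent(eps, c(-1, 1, 1, 1)), "positive")
})

test_that("bounds sandwich the exact MFPT on fixtures and random networks", {
  check_sandwich <- function(net, tol = 1e-9) {
    fns <- enumerate_level_functions(net)
    checked <- 0
    for (f in fns) {
      an <- tryCatch(mfpt_analysis(net, f), error = function(e) NULL)
      if (is.null(an)) next     # standing assumption or empty level
      b <- an$bounds
      if (!any(is.na(an$exact_up))) {
        if (!is.na(b$lower_up)) {
          expect_true(all(b$lower_up <= an$exact_up * (1 + tol) + tol))
          checked <- checked + 1
        }
        if (!is.na(b$upper_up)) {
          expect_true(all(an$exact_up <= b$upper_up * (1 + tol) + tol))
          checked <- checked + 1
        }
      }
      if (!any(is.na(an$exact_down))) {
        if (!is.na(b$lower_down)) {
          expect_true(all(b$lower_down <= an$exact_down * (1 + tol) + tol))
          checked <- checked + 1
        }
        if (!is.na(b$upper_down)) {
          expect_true(all(an$exact_down <= b$upper_down * (1 + tol) + tol))
          checked <- checked + 1
        }
      }
    }
    checked
  }
  total <- 0
  total <- total + check_sandwich(scrn_cascade(1.2, 0.6, 3))
  total <- total + check_sandwich(scrn_histone(eps = 0.4, d_tot = 2))
  total <- total + check_sandwich(scrn_biparallel(1, 2, 0.5, 1, 2))
  total <- total + check_sandwich(scrn_coupled())
  for (seed in 1:20) {
    net <- random_unit_transfer(d = 2 + seed %% 4, density = 0.6,
                                bipartite = TRUE, seed = seed,
                                tot_per_species = 2)
    total <- total + check_sandwich(net)
  }
  expect_gt(total, 20)
})

test_that("cascade bounds and exact MFPT decrease in either rate constant", {
  grid <- c(0.5, 1, 1.5, 2, 2.5)
  lower <- upper <- exact <- matrix(NA, 5, 5)
  for (i in seq_along(grid)) for (j in seq_along(grid)) {
    an <- mfpt_analysis(scrn_cascade(grid[i], grid[j], 2), c(1, 2))
    lower[i, j] <- an$bounds$lower_up
    upper[i, j] <- an$bounds$upper_up
    exact[i, j] <- cascade_hypoexp_mfpt(grid[i], grid[j], 2)
  }
  for (m in list(lower, upper, exact)) {
    expect_true(all(diff(m) < 0))        # decreasing in alpha (rows)
    expect_true(all(diff(t(m)) < 0))     # decreasing in beta (columns)
  }
})

test_that("bound formulas equal exact solves of the bounding chains", {
  for (net in list(scrn_histone(eps = 0.5, d_tot = 2), scrn_coupled())) {
    sp <- projected_state_space(net)
    gen <- projected_generator(net, sp)
    f <- find_fn(enumerate_level_functions(net), c(1, -1))
    dec <- level_decomposition(f, sp, gen)
    summ <- tryCatch(level_rate_summary(f, sp, gen, dec),
                     error = function(e) NULL)
    if (is.null(summ)) next
    b <- mfpt_bounds(summ)
    zl <- as.character(dec$l:(dec$u - 1))
    zu <- as.character((dec$l + 1):dec$u)
    if (!is.na(b$lower_up))
      expect_equal(b$lower_up,
                   bd_exact_mfpt(dec$l, dec$u, summ$lambda_max[zl],
                                 summ$gamma_min[zu], dec$l, dec$u),
                   tolerance = 1e-9)
    if (!is.na(b$upper_down)) {
      expect_equal(b$upper_down,
                   bd_exact_mfpt(dec$l, dec$u, summ$lambda_max[zl],
                                 summ$gamma_min[zu], dec$u, dec$l),
                   tolerance = 1e-9)
    }
    # and the level process of the fast bounding chain itself
    if (!is.na(b$lower_up)) {
      bg <- bounding_generators(summ)
      bottom <- dec$sets[[as.character(dec$l)]]
      top <- dec$sets[[as.character(dec$u)]]
      expect_equal(unique(round(exact_mfpt(bg$Q_fast, top, bottom), 9)),
                   round(b$lower_up, 9))
    }
  }
})
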
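test_that("state spaces enumerate the conservation simplex products", {
  sp <- projected_state_space(scrn_cascade(n_tot = 2))
  expect_equal(nrow(sp$states), 6)                 # C(2+2, 2)
  expect_equal(colnames(sp$states), c("W", "Y"))

  sp2 <- projected_state_space(scrn_coupled(n1 = 2, n2 = 3))
  expect_equal(nrow(sp2$states), 12)               # (N1+1)(N2+1) grid
  expect_equal(colnames(sp2$states), c("S1", "S3"))

  expect_equal(nrow(projected_state_space(two_species_net(tot = 5))$states), 6)

  degen <- two_species_net(tot = 0)
  expect_error(projected_state_space(degen), "degenerate")
})

test_that("generator rates equal the lifted mass-action propensities", {
  alpha <- 1.3; beta <- 0.8
  net <- scrn_cascade(alpha, beta, 2)
  sp <- projected_state_space(net)
  gen <- projected_generator(net, sp)
  s10 <- match("1,0", sp$keys)
  s20 <- match("2,0", sp$keys)
  s01 <- match("0,1", sp$keys)
  expect_equal(gen$Q[s10, s20], alpha * 1)   # alpha (N_tot - x1 - x2)
  expect_equal(gen$Q[s10, s01], beta * 1)    # beta x1
  expect_equal(as.numeric(Matrix::rowSums(gen$Q)), rep(0, nrow(sp$states)))

  # histone rows reproduce the published rate functions at every state
  eps <- 0.2; mu <- 1.5; bt <- 0.7; V <- 1.1; dtot <- 3
  h <- scrn_histone(eps, mu, bt, dtot, kA_W0 = 0.4, kA_W = 1.1, kA_M = 0.9,
                    kA_E = 1.2, kR_W0 = 0.7, kR_W = 0.3, kR_M = 1.5, V = V)
  sph <- projected_state_space(h)
  genh <- projected_generator(h, sph)
  for (s in seq_len(nrow(sph$states))) {
    x1 <- sph$states[s, 1]; x2 <- sph$states[s, 2]; D <- dtot - x1 - x2
    want <- c(D * (0.4 + 1.1 + 0.9 * x2 / V),
              x2 * (eps * 0.9 * dtot / V + x1 * 1.2 / V),
              D * (0.7 + 0.3 + 1.5 * x1 / V),
              x1 * mu * (eps * 0.9 * dtot * bt / V + x2 * 1.2 / V))
    for (k in 1:4) {
      tgt <- sph$states[s, ] + sph$info$vcheck[, k]
      t_idx <- match(paste(tgt, collapse = ","), sph$keys)
      if (!is.na(t_idx))
        expect_equal(as.numeric(genh$Q[s, t_idx]), unname(want[k]))
    }
  }
  expect_equal(as.numeric(Matrix::rowSums(genh$Q)),
               rep(0, nrow(sph$states)), tolerance = 1e-12)
})

test_that("level decompositions locate the published extreme levels", {
  n_tot <- 3
  net <- scrn_cascade(n_tot = n_tot)
  sp <- projected_state_space(net)
  gen <- projected_generator(net, sp)
  dec <- level_decomposition(find_fn(enumerate_level_functions(net), c(1, 2)),
                             sp, gen)
  expect_equal(dec$l, 0)
  expect_equal(dec$u, 2 * n_tot)
  expect_equal(sp$states[dec$sets[["0"]], ], c(W = 0, Y = 0))
  expect_equal(sp$states[dec$sets[[as.character(2 * n_tot)]], ],
               c(W = 0, Y = n_tot))

  dtot <- 2
  h <- scrn_histone(d_tot = dtot)
  sph <- projected_state_space(h)
  genh <- projected_generator(h, sph)
  dech <- level_decomposition(find_fn(enumerate_level_functions(h), c(1, -1)),
                              sph, genh)
  expect_equal(c(dech$l, dech$u), c(-dtot, dtot))
  expect_equal(sph$states[dech$sets[[as.character(-dtot)]], ],
               c(DR = 0, DA = dtot))
  expect_equal(sph$states[dech$sets[[as.character(dtot)]], ],
               c(DR = dtot, DA = 0))

  fc <- scrn_full_chromatin(d_tot = dtot)
  spf <- projected_state_space(fc)
  genf <- projected_generator(fc, spf)
  decf <- level_decomposition(
    find_fn(enumerate_level_functions(fc), c(2, -1, 1, 1)), spf, genf)
  expect_equal(c(decf$l, decf$u), c(-dtot, 2 * dtot))

  # level-set partition covers the space exactly once
  expect_equal(sum(vapply(decf$sets, length, integer(1))), nrow(spf$states))

  # a linear function whose increments are not +/-1 is rejected
  bad <- coclique:::.make_level_function(
    c(2, 1), c(1, -1, 2, -2), colnames(sph$states))
  expect_error(level_decomposition(bad, sph, genh), "not a coclique")
})

test_that("every transition changes the level by exactly one", {
  nets <- list(scrn_cascade(), scrn_histone(), scrn_biparallel(),
               scrn_coupled())
  for (net in nets) {
    sp <- projected_state_space(net)
    gen <- projected_generator(net, sp)
    for (f in enumerate_level_functions(net)) {
      z <- as.numeric(sp$states %*% f$b)
      for (k in seq_along(gen$moves)) {
        mv <- gen$moves[[k]]
        if (!nrow(mv)) next
        expect_true(all(abs(z[mv[, "to"]] - z[mv[, "from"]]) == 1))
      }
    }
  }
})

test_that("rate extrema bracket the per-state rates; cascade has no decrease", {
  net <- scrn_cascade(1, 2, 2)
  sp <- projected_state_space(net)
  gen <- projected_generator(net, sp)
  f <- find_fn(enumerate_level_functions(net), c(1, 2))
  summ <- level_rate_summary(f, sp, gen)
  expect_equal(summ$G_plus, c(1L, 2L))
  expect_equal(length(summ$G_minus), 0)
  expect_true(all(summ$gamma == 0))

  # published min/max expressions of the coupled network at unit rates
  k <- c(1, 1, 1, 1); N1 <- 2; N2 <- 2; N3 <- 1
  cpl <- scrn_coupled(k[1], k[2], k[3], k[4], N1, N2, N3)
  spc <- projected_state_space(cpl)
  genc <- projected_generator(cpl, spc)
  fc <- find_fn(enumerate_level_functions(cpl), c(1, 1))
  sc <- level_rate_summary(fc, spc, genc)
  for (z in 0:(N1 + N2)) {
    grid <- expand.grid(x1 = 0:N1, x3 = 0:N2)
    grid <- grid[grid$x1 + grid$x3 == z, , drop = FALSE]
    lam <- k[2] * (N1 - grid$x1) * N3 + k[4] * (N2 - grid$x3)
    gam <- k[1] * grid$x1 * (N2 - grid$x3) + k[3] * grid$x3
    zc <- as.character(z)
    expect_equal(sc$lambda_max[[zc]], max(lam))
    expect_equal(sc$lambda_min[[zc]], min(lam))
    expect_equal(sc$gamma_max[[zc]], max(gam))
    expect_equal(sc$gamma_min[[zc]], min(gam))
  }
  expect_true(all(sc$gamma_min[as.character(1:(N1 + N2))] > 0))

  # extrema bracket per-state rates on every fixture (functions violating
  # the feasible-move standing assumption are excluded by a typed error)
  for (net in list(scrn_histone(), scrn_biparallel())) {
    sp <- projected_state_space(net)
    gen <- projected_generator(net, sp)
    for (f in enumerate_level_functions(net)) {
      dec <- level_decomposition(f, sp, gen)
      s <- tryCatch(level_rate_summary(f, sp, gen, dec),
                    error = function(e) NULL)
      if (is.null(s)) next
      for (z in dec$levels) {
        idx <- dec$sets[[as.character(z)]]
        zc <- as.character(z)
        expect_true(all(s$lambda[idx] <= s$lambda_max[[zc]] + 1e-12))
        expect_true(all(s$lambda[idx] >= s$lambda_min[[zc]] - 1e-12))
        expect_true(all(s$gamma[idx] <= s$gamma_max[[zc]] + 1e-12))
        expect_true(all(s$gamma[idx] >= s$gamma_min[[zc]] - 1e-12))
      }
    }
  }
})

test_that("lifting a projected state and re-projecting is the identity", {
  for (net in list(scrn_coupled(), scrn_full_chromatin())) {
    sp <- projected_state_space(net)
    info <- sp$info
    for (s in seq_len(nrow(sp$states))) {
      full <- coclique:::.lift_state(sp, sp$states[s, ])
      # totals conserved per component
      g <- info$graph
      for (q in seq_len(g$n_components))
        expect_equal(sum(full[which(g$component == q)]), sp$totals[q])
      # re-project: take the coordinate species back out
      expect_equal(unname(full[info$coord_species]),
                   unname(sp$states[s, ]))
    }
  }
})

test_that("bounding generators project to birth-death chains on the levels", {
  for (net in list(scrn_histone(d_tot = 2), scrn_biparallel(s_tot = 2),
                   scrn_coupled())) {
    sp <- projected_state_space(net)
    gen <- projected_generator(net, sp)
    f <- enumerate_level_functions(net)[[1]]
    dec <- level_decomposition(f, sp, gen)
    summ <- level_rate_summary(f, sp, gen, dec)
    bg <- bounding_generators(summ)
    z <- dec$level_of
    for (gen_case in list(list(Q = bg$Q_fast, up = summ$lambda_max,
                               down = summ$gamma_min),
                          list(Q = bg$Q_slow, up = summ$lambda_min,
                               down = summ$gamma_max))) {
      Q <- gen_case$Q
      expect_equal(as.numeric(Matrix::rowSums(Q)), rep(0, nrow(sp$states)),
                   tolerance = 1e-12)
      for (s in seq_len(nrow(sp$states))) {
        zc <- as.character(z[s])
        up_tot <- sum(Q[s, z == z[s] + 1])
        down_tot <- sum(Q[s, z == z[s] - 1])
        if (z[s] < dec$u)
          expect_equal(up_tot, gen_case$up[[zc]], tolerance = 1e-12)
        if (z[s] > dec$l)
          expect_equal(down_tot, gen_case$down[[zc]], tolerance = 1e-12)
      }
    }
  }
})
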
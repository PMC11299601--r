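test_that("sample cost is the squared Frobenius residual", {
  psi <- matrix(2 + 0i, 1, 1)
  expect_equal(sample_cost(psi, psi), 0)
  expect_equal(sample_cost(psi, matrix(3 + 0i, 1, 1)), 1)
  a <- random_complex(5, 5, 1); b <- random_complex(5, 5, 2)
  expect_equal(sample_cost(3 * a, 3 * b), 9 * sample_cost(a, b),
               tolerance = 1e-12)
})

test_that("subgradient step follows the scalar iteration oracle and clips at the threshold", {
  # 1-D quadratic g(x) = x^2: from x = 2 with xi = 0, lambda = 1
  x <- 2
  x <- subgradient_step(x, grad = 4, g_value = 4, xi = 0, lambda = 1)
  expect_equal(x, 1)
  x <- subgradient_step(x, grad = 2, g_value = 1, xi = 0, lambda = 1)
  expect_equal(x, 0.5)

  # threshold met at the start: immediate fixed point
  expect_equal(subgradient_step(2, 4, 4, xi = 4, lambda = 1), 2)

  # zero gradient at positive thresholded cost has no direction
  expect_error(subgradient_step(2, 0, 4, 0, 1),
               class = "ptycrisp_no_direction")
})

test_that("step size function G matches the scalar oracle and ignores global phase", {
  Q <- matrix(2 + 0i, 1, 1); delta <- matrix(1 + 0i, 1, 1)
  expect_equal(step_size_G(Q, delta, e = 1, xi = 0), 0.25)
  expect_equal(step_size_G(Q, delta, e = 1, xi = 1), 0)
  expect_equal(step_size_G(Q, delta, e = 0.5, xi = 1), 0)
  Qr <- random_complex(4, 4, 3); dr <- random_complex(4, 4, 4)
  expect_equal(step_size_G(Qr * exp(0.7i), dr, 2, 0.1),
               step_size_G(Qr, dr, 2, 0.1), tolerance = 1e-12)
  expect_error(step_size_G(matrix(0i, 2, 2), matrix(0i, 2, 2), 1, 0),
               class = "ptycrisp_no_direction")
})

test_that("clipping caps the coefficient at nu/|Q|^2_max", {
  Q <- matrix(2 + 0i, 1, 1)
  expect_equal(clip_G(0.1, Q, nu = 1), 0.1)
  expect_equal(clip_G(10, Q, nu = 1), 0.25)
  # scale-adaptive cap: nu = |P|_max gives 1/|P|_max
  expect_equal(clip_G(10, Q, nu = max(Mod(Q))), 0.5)
  expect_error(clip_G(1, matrix(0i, 1, 1), 1), "degenerate")
})

test_that("crisp_direction reproduces the clipped ePIE-equivalent scalar case", {
  O <- matrix(1 + 0i, 1, 1); P <- matrix(2 + 0i, 1, 1)
  psip <- matrix(3 + 0i, 1, 1)
  d <- crisp_direction(O, P, psip, xi = 0, nu_o = 1, nu_p = 1)
  expect_equal(d$e, 1)
  expect_equal(d$coef_o, 0.25)  # G = 1/4 equals the cap 1/4
  expect_equal(d$D_o, matrix(0.5 + 0i, 1, 1))
  expect_equal(O + 1 * d$D_o, matrix(1.5 + 0i, 1, 1))  # ePIE's update

  # thresholded: no movement
  d0 <- crisp_direction(O, P, psip, xi = 2, nu_o = 1, nu_p = 1)
  expect_equal(d0$D_o, matrix(0 + 0i, 1, 1))
  expect_equal(d0$D_p, matrix(0 + 0i, 1, 1))

  # zero residual
  dz <- crisp_direction(O, P, P * O, xi = 0, nu_o = 1, nu_p = 1)
  expect_equal(dz$e, 0)
  expect_equal(dz$D_o, matrix(0 + 0i, 1, 1))
})

test_that("applied coefficients never exceed the clipping cap", {
  for (i in 1:50) {
    On <- random_complex(6, 6, 100 + i)
    Pn <- random_complex(6, 6, 200 + i)
    psip <- random_complex(6, 6, 300 + i)
    xi <- withr::with_seed(400 + i, runif(1, 0, 5))
    d <- crisp_direction(On, Pn, psip, xi, nu_o = 1, nu_p = 1)
    expect_lte(d$coef_o, 1 / max(Mod(Pn))^2 + 1e-15)
    expect_lte(d$coef_p, 1 / max(Mod(On))^2 + 1e-15)
    d2 <- crisp_direction(On, Pn, psip, xi,
                          nu_o = max(Mod(Pn)), nu_p = max(Mod(On)))
    expect_lte(d2$coef_o, 1 / max(Mod(Pn)) + 1e-15)
    expect_lte(d2$coef_p, 1 / max(Mod(On)) + 1e-15)
  }
})

test_that("xi tuning follows c * mean(e) and initialize_xi matches a direct recomputation", {
  expect_equal(update_xi(c(1, 3), 0.5), 1)
  expect_equal(update_xi(rep(2.5, 7), 0.3), 0.75)
  expect_equal(update_xi(c(1, 3), 1e-6), 2e-6)
  expect_error(update_xi(numeric(0), 0.5), "empty")

  sim <- tiny_problem(seed = 9, noise = "poisson", I0 = 1e6)
  init <- initializers_for(sim)
  xi0 <- initialize_xi(sim$dataset, sim$scan, init$object, init$probe, 0.4)
  # direct recomputation
  e <- numeric(9)
  for (n in 1:9) {
    s <- split_shift(sim$scan$positions[n, ])
    Pn <- shift_probe_subpixel(init$probe$values, s$s_sub)
    On <- object_patch(init$object, s$s_int, dim(init$probe$values))
    psi <- Pn * On
    e[n] <- sample_cost(psi, revised_exit_wave(psi, sim$dataset$intensities[n, , ]))
  }
  expect_equal(xi0, 0.4 * mean(e), tolerance = 1e-12)
  expect_equal(initialize_xi(sim$dataset, sim$scan, init$object,
                             init$probe, 0.2), xi0 / 2, tolerance = 1e-12)

  # noise-free data at the truth: all costs vanish
  simc <- tiny_problem(seed = 9, noise = "clean")
  xi_t <- initialize_xi(simc$dataset, simc$scan, simc$truth$object,
                        simc$truth$probe, 0.5)
  expect_lt(xi_t / initialize_xi(simc$dataset, simc$scan, init$object,
                                 init$probe, 0.5), 1e-12)
})

test_that("the xi trace obeys xi[k+1] = c * mean(e[k]) at every iteration", {
  sim <- tiny_problem(seed = 2, noise = "poisson", I0 = 1e6)
  init <- initializers_for(sim)
  res <- run_crisp(sim$dataset, sim$scan, init$object, init$probe,
                   crisp_params(lambda_o = 0.5, lambda_p = 0.3,
                                c_tune = 0.35, K = 8, seed = 4),
                   trace_rf = FALSE)
  expect_length(res$xi_trace, 9)
  expect_equal(res$xi_trace[2:9], 0.35 * res$cost, tolerance = 1e-12)
  expect_equal(res$xi_trace[1],
               initialize_xi(sim$dataset, sim$scan, init$object,
                             init$probe, 0.35), tolerance = 1e-12)
})

test_that("a CRISP sweep is a fixed point when every sample cost is below xi", {
  sim <- tiny_problem(seed = 6, noise = "clean")
  res <- run_crisp(sim$dataset, sim$scan, sim$truth$object, sim$truth$probe,
                   crisp_params(K = 2, xi_mode = "fixed", xi_fixed = 1e6,
                                c_tune = 0.5, seed = 1), trace_rf = FALSE)
  expect_equal(res$object$values, sim$truth$object$values, tolerance = 1e-12)
  expect_equal(res$probe$values, sim$truth$probe$values, tolerance = 1e-10)
})

test_that("clipped CRISP with pinned xi reproduces the ePIE trajectory", {
  sim <- tiny_problem(seed = 3, noise = "clean", canvas = c(40, 40),
                      window = c(16, 16), rows = 3, cols = 3, step = 5)
  init <- initializers_for(sim)
  K <- 10
  ep <- run_pie(sim$dataset, sim$scan, init$object, init$probe,
                pie_params(alpha_o = 0.9, alpha_p = 0.35, K = K, seed = 11),
                variant = "epie", trace_rf = FALSE)
  cr <- run_crisp(sim$dataset, sim$scan, init$object, init$probe,
                  crisp_params(lambda_o = 0.9, lambda_p = 0.35,
                               nu = "epie_like", c_tune = 0.5, K = K,
                               seed = 11, xi_mode = "fixed", xi_fixed = 0,
                               force_cap = TRUE), trace_rf = FALSE)
  expect_lt(max(Mod(cr$object$values - ep$object$values)) /
              max(Mod(ep$object$values)), 1e-8)
  expect_lt(max(Mod(cr$probe$values - ep$probe$values)) /
              max(Mod(ep$probe$values)), 1e-8)
})

test_that("CRISP runs are reproducible under a fixed seed", {
  sim <- tiny_problem(seed = 4, noise = "poisson", I0 = 1e6)
  init <- initializers_for(sim)
  p <- crisp_params(K = 3, seed = 8, c_tune = 0.2)
  r1 <- run_crisp(sim$dataset, sim$scan, init$object, init$probe, p,
                  trace_rf = FALSE)
  r2 <- run_crisp(sim$dataset, sim$scan, init$object, init$probe, p,
                  trace_rf = FALSE)
  expect_identical(r1$object$values, r2$object$values)
  expect_identical(r1$xi_trace, r2$xi_trace)
})

test_that("toy subgradient projection shows the three threshold regimes", {
  # E = 0, xi = 0: converges to the minimizer like gradient descent
  conv <- run_toy_subgradient(quadratic_bowl(E = 0), xi = 0, lambda = 1,
                              K = 200)
  expect_false(conv$diverged)
  expect_lt(sum(conv$points[nrow(conv$points), ]^2), 1e-12)

  # E > 0, xi = 0: the step blows up near the minimizer; flagged
  div <- run_toy_subgradient(quadratic_bowl(E = 1), xi = 0, lambda = 1,
                             K = 2000)
  expect_true(div$diverged)

  # E > 0, xi > E: settles inside the sublevel set {g <= xi}
  stop_in <- run_toy_subgradient(quadratic_bowl(E = 1), xi = 1.5,
                                 lambda = 1, K = 2000)
  expect_false(stop_in$diverged)
  expect_true(stop_in$stopped_inside)
  expect_lte(stop_in$g_values[length(stop_in$g_values)], 1.5)

  # clipping tames the blow-up of the E > 0, xi = 0 case
  clipped <- run_toy_subgradient(quadratic_bowl(E = 1), xi = 0, lambda = 1,
                                 K = 500, clip = 0.25)
  expect_false(clipped$diverged)
})
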
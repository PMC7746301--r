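test_that("Hill activation matches its closed form and saturates", {
  f <- response_function("activation", 1, 1, 2)
  expect_identical(hill_activation(0, f), 0)
  expect_equal(hill_activation(1, f), 0.5)
  f2 <- response_function("activation", 2, 4, 2)
  expect_equal(hill_activation(1e3, f2), 2 / 4, tolerance = 1e-5)
  expect_error(hill_activation(-1, f), "nonnegative")
  expect_error(response_function("activation", -1, 1, 2), "positive")
  expect_error(response_function("activation", 1, 1, 0.5), "allow_shallow")
  expect_silent(response_function("activation", 1, 1, 0.5,
                                  allow_shallow = TRUE))
})

test_that("Hill inhibition matches its closed form and decays", {
  h <- response_function("inhibition", 1, 1, 2)
  expect_equal(hill_inhibition(0, h), 1)
  expect_equal(hill_inhibition(1, h), 0.5)
  expect_lt(hill_inhibition(1e3, h), 1e-5)
  h3 <- response_function("inhibition", 3.7, 0.2, 4)
  expect_equal(hill_inhibition(0, h3), 3.7)
})

test_that("responses are monotone for random parameter draws", {
  set.seed(11)
  for (i in 1:200) {
    par <- exp(runif(2, log(0.1), log(10)))
    n <- sample(c(1, 2, 4), 1)
    x <- sort(runif(2, 0, 5))
    f <- response_function("activation", par[1], par[2], n)
    h <- response_function("inhibition", par[1], par[2], n)
    expect_gt(hill_activation(x[2], f), hill_activation(x[1], f))
    expect_lt(hill_inhibition(x[2], h), hill_inhibition(x[1], h))
  }
})

test_that("rhs at the origin with unit parameters matches hand evaluation", {
  # f(0) = 0 and h(0) = gamma = 1, so with every scale = 1, tau = 1, u = 0:
  # a' = h6(0) = 1; k' = f1(0) + h4(0) = 0 + 1 = 1; c' = h2(0) = 1;
  # m' = h7(0) + h1(0) + f2(0) = 2; p' = mu * h5(0) = mu; g' = h3(0) = 1
  for (mu in c(0, 1, 2.5)) {
    p <- unit_parameterization(hill = 1, u = 0, mu = mu)
    r <- model_rhs(rep(0, 6), p)
    expect_equal(unname(r), c(1, 1, 1, 2, mu, 1))
  }
  # tau rescales the rates
  p <- unit_parameterization(hill = 1, tau = 2, u = 0, mu = 1)
  expect_equal(unname(model_rhs(rep(0, 6), p)), c(1, 1, 1, 2, 1, 1) / 2)
})

test_that("u enters only the OXPHOS equation, decreasingly", {
  p0 <- unit_parameterization(hill = 2, u = 0.5)
  p1 <- unit_parameterization(hill = 2, u = 1.5)
  set.seed(3)
  for (i in 1:5) {
    x <- runif(6, 0, 2)
    r0 <- model_rhs(x, p0); r1 <- model_rhs(x, p1)
    expect_lt(r1[["m"]], r0[["m"]])
    expect_equal(r1[-4], r0[-4])
  }
})

test_that("rhs vanishes at the knockout closed-form steady state", {
  p <- fixture_params(mu = 0)
  cf <- knockout_equilibrium_closed_form(p)
  expect_lt(max(abs(model_rhs(cf$state, p))), 1e-10)
})

test_that("analytic Jacobian matches a central-difference oracle", {
  p <- fixture_params()
  set.seed(21)
  for (rep in 1:10) {
    x <- runif(6, 0.05, 3)
    J <- model_jacobian(x, p)
    Jfd <- matrix(0, 6, 6)
    eps <- 1e-6
    for (j in 1:6) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
      Jfd[, j] <- (model_rhs(xp, p) - model_rhs(xm, p)) / (2 * eps)
    }
    expect_equal(unname(unclass(J)), Jfd, tolerance = 1e-6)
  }
})

test_that("Jacobian sign pattern is state-independent and matches S", {
  p <- fixture_params()
  S <- interaction_matrix(p$network)
  Snum <- matrix(c(`-` = -1, `0` = 0, `+` = 1)[unclass(S)], 6, 6)
  set.seed(5)
  for (rep in 1:10) {
    x <- runif(6, 0.01, 5)
    J <- unclass(model_jacobian(x, p))
    off <- row(J) != col(J)
    expect_identical(sign(J)[off], Snum[off])
    expect_true(all(diag(J) < 0))
  }
  # knocked-out edge: (p, k) entry exactly zero at mu = 0
  p0 <- fixture_params(mu = 0)
  expect_identical(model_jacobian(runif(6, 0.1, 2), p0)["p", "k"], 0)
})

test_that("fast compiled paths agree with the reference implementation", {
  set.seed(9)
  for (rep in 1:10) {
    p <- sample_parameterization(seed = 300 + rep)
    p$mu <- runif(1, 0, 5)
    x <- runif(6, 0, 3)
    expect_equal(
      loopstate:::prod_fast(x, p$compiled, p$u, p$mu),
      unname(loopstate:::model_production(x, p)))
    expect_equal(
      loopstate:::prodjac_fast(x, p$compiled, p$u, p$mu),
      unname(unclass(model_jacobian(x, p)) * p$tau))
  }
})

test_that("trajectories stay nonnegative and bounded in the production box", {
  p <- fixture_params()
  ub <- loopstate:::equilibrium_box(p)
  set.seed(7)
  for (rep in 1:20) {
    x0 <- runif(6, 0, 2) * ub
    tr <- simulate(p, x0, t_end = 40, n_out = 41)
    expect_true(all(tr$states >= 0))
    # after a transient every variable is under its production bound
    expect_true(all(tr$states[41, ] <= ub))
  }
})

test_that("parameterization validation catches the documented errors", {
  p <- fixture_params()
  expect_error(model_rhs(rep(0, 5), p), "length")
  expect_error(model_rhs(c(-1, rep(0, 5)), p), "nonnegative")
  net <- als_network()
  resp <- p$responses
  expect_error(model_parameterization(net, resp[-1], p$tau), "f1")
  bad_tau <- p$tau; bad_tau[1] <- -1
  expect_error(model_parameterization(net, resp, bad_tau), "positive")
  expect_error(model_parameterization(net, resp, p$tau[-1]), "missing")
  # activation response on an inhibition edge
  resp2 <- resp
  resp2$h5 <- response_function("activation", 1, 1, 2)
  expect_error(model_parameterization(net, resp2, p$tau), "h5")
})

test_that("signed_network validates nodes and edges", {
  expect_error(signed_network(c("x", "x"),
                              data.frame(from = "x", to = "x", sign = 1L,
                                         label = "e")), "unique")
  expect_error(signed_network("x",
                              data.frame(from = "x", to = "z", sign = 1L,
                                         label = "e")), "unknown node")
  expect_error(signed_network("x",
                              data.frame(from = "x", to = "x", sign = 2L,
                                         label = "e")), "sign")
  als <- als_network()
  expect_identical(als$nodes, c("a", "k", "c", "m", "p", "g"))
  expect_identical(nrow(als$edges), 8L)
  expect_identical(als$input_edges$label, "h7")
})
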
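test_that("knockout closed form matches hand evaluation at unit parameters", {
  p <- unit_parameterization(hill = 2, u = 0, mu = 0)
  cf <- knockout_equilibrium_closed_form(p)
  # p = 0; g = h3(0) = 1; c = h2(1) = 1/2; m = h7(0) + h1(1) + f2(0) = 3/2;
  # a = h6(3/2) = 1/(1 + 2.25) = 4/13; k = f1(a) + h4(1/2)
  a <- 1 / (1 + 1.5^2)
  k <- a^2 / (1 + a^2) + 1 / (1 + 0.25)
  expect_equal(unname(cf$state), c(a, k, 0.5, 1.5, 0, 1), tolerance = 1e-10)
  expect_equal(a, 0.30769, tolerance = 1e-4)
  expect_equal(k, 0.88648, tolerance = 1e-4)
})

test_that("closed form requires mu = 0 and pins PPP at exactly zero", {
  expect_error(knockout_equilibrium_closed_form(fixture_params(mu = 2)),
               "mu = 0")
  set.seed(41)
  for (rep in 1:5) {
    p <- sample_parameterization(seed = 600 + rep)
    p$mu <- 0
    expect_identical(knockout_equilibrium_closed_form(p)$state[["p"]], 0)
  }
})

test_that("closed form agrees with multistart search on random instances", {
  # scaled-down version of the acceptance check (30 instead of 100 draws)
  set.seed(8)
  for (rep in 1:30) {
    p <- sample_parameterization(seed = 700 + rep)
    p$mu <- 0
    cf <- knockout_equilibrium_closed_form(p)
    eqs <- find_equilibria(p, n_starts = 10, seed = rep,
                           simulate_starts = FALSE)
    expect_length(eqs, 1)
    expect_true(eqs[[1]]$stable)
    expect_lt(max(abs(eqs[[1]]$state - cf$state)), 1e-8)
  }
})

test_that("the u -> infinity limit removes the input term from OXPHOS", {
  p <- fixture_params(mu = 0)
  p$u <- 1e9
  cf <- knockout_equilibrium_closed_form(p)
  m_limit <- eval_response(eval_response(0, p$responses$h3),
                           p$responses$h1) +
    eval_response(0, p$responses$f2)
  expect_equal(cf$state[["m"]], m_limit, tolerance = 1e-8)
})

test_that("knockout_edge removes the edge and its loops", {
  p <- fixture_params()
  ko5 <- knockout_edge(p, "h5")
  expect_identical(ko5$mu, 0)
  expect_false("h5" %in% ko5$network$edges$label)
  expect_length(enumerate_feedback_loops(interaction_matrix(ko5$network)), 0)
  ko1 <- knockout_edge(p, "f1")
  loops <- enumerate_feedback_loops(interaction_matrix(ko1$network))
  expect_length(loops, 1)
  expect_identical(loops[[1]]$nodes, c("c", "k", "p", "g"))
  expect_error(knockout_edge(p, "nope"), "valid edges")
})

test_that("h5 knockout leaves a single stable equilibrium", {
  ko <- knockout_edge(fixture_params(), "h5")
  eqs <- find_equilibria(ko, n_starts = 15, seed = 3)
  expect_length(eqs, 1)
  expect_true(eqs[[1]]$stable)
  cf <- knockout_equilibrium_closed_form(ko)
  expect_lt(max(abs(eqs[[1]]$state - cf$state)), 1e-8)
})

# one moderately fine sweep reused by several assertions below
diagram <- sweep_mu(fixture_params(),
                    mu_grid = exp(seq(log(0.5), log(80),
                                      length.out = 50)),
                    seed = 5, n_starts = 15)

test_that("the mu sweep shows the 1 -> 3 -> 1 equilibrium pattern", {
  expect_identical(as.integer(rle(diagram$counts$n_total)$values),
                   c(1L, 3L, 1L))
  expect_identical(as.integer(rle(diagram$counts$n_stable)$values),
                   c(1L, 2L, 1L))
})

test_that("folds pair up and bracket the bistable window", {
  expect_length(diagram$folds, 2)
  expect_false(diagram$boundary_fold_flag)
  w <- diagram$window
  expect_lt(diagram$folds[1], w[1])
  expect_gt(diagram$folds[2], w[2])
  # pinned window endpoints (grid-certified at fixture creation) lie inside
  pin <- loopstate:::reference_fixture_values()$window
  expect_lt(diagram$folds[1], pin[1])
  expect_gt(diagram$folds[2], pin[2])
})

test_that("stable-branch PFK3 is monotone (nonincreasing) in mu", {
  # mu scales the whole PPP production term mu * h5(k), so increasing mu
  # is a positive persistent input on the PPP equation; the influence
  # matrix (column PPP, row PFK3 = '-') forces steady-state PFK3 down.
  pts <- diagram$points[diagram$points$stable, ]
  for (b in unique(pts$branch)) {
    kb <- pts$k[pts$branch == b][order(pts$mu[pts$branch == b])]
    if (length(kb) > 1) expect_true(all(diff(kb) < 1e-8))
  }
  # and the unique low-mu equilibrium is the high-PFK3 (pathological) one
  lo <- diagram$points[diagram$points$mu == min(diagram$grid), ]
  hi <- diagram$points[diagram$points$mu == max(diagram$grid), ]
  expect_gt(lo$k[1], hi$k[1])
})

test_that("dominant eigenvalues stay real along the sweep", {
  # monotone system: instability can only arise through a real eigenvalue
  p <- fixture_params()
  for (i in seq_len(nrow(diagram$points))) {
    row <- diagram$points[i, ]
    p$mu <- row$mu
    J <- model_jacobian(unlist(row[node_order]), p)
    ev <- eigen(J, only.values = TRUE)$values
    dom <- ev[which.max(Re(ev))]
    expect_lt(abs(Im(dom)), 1e-8)
  }
})

test_that("a grid entirely below the first fold has one branch, no folds", {
  d <- sweep_mu(fixture_params(), mu_grid = seq(0.5, 2, length.out = 8),
                seed = 6, n_starts = 12)
  expect_length(d$folds, 0)
  expect_null(d$window)
  expect_identical(unique(d$counts$n_total), 1L)
})

test_that("hysteresis: path dependence inside the fold bracket only", {
  w <- loopstate:::reference_fixture_values()$window
  folds <- diagram$folds
  up <- exp(seq(log(w[1] / 3), log(w[2] * 3), length.out = 25))
  h <- hysteresis_run(fixture_params(), c(up, rev(up)))
  nu <- length(up)
  k_up <- h$k[seq_len(nu)]
  k_dn <- rev(h$k[nu + seq_len(nu)])
  inside <- up > w[1] & up < w[2]
  outside <- up < folds[1] | up > folds[2]
  expect_true(any(abs(k_up[inside] - k_dn[inside]) > 1e-2))
  expect_true(all(abs(k_up[outside] - k_dn[outside]) < 1e-5))
  # inside the window the up sweep still tracks the high-PFK3 branch it
  # entered on, the down sweep the low-PFK3 branch
  expect_true(all(k_up[inside] > k_dn[inside]))
  # once the down sweep (increasing suppression) exits below the lower
  # fold it sits on the unique high-PFK3 pathological branch
  expect_gt(k_dn[1], k_dn[nu] + 1)
})
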
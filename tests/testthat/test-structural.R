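als_S <- interaction_matrix(als_network())
als_Su <- input_sign_vector(als_network())

test_that("ALS interaction matrix reproduces the printed sign pattern", {
  expected <- matrix(c(
    "-", "0", "0", "-", "0", "0",   # on AMPK
    "+", "-", "-", "0", "0", "0",   # on PFK3
    "0", "0", "-", "0", "0", "-",   # on APC^Cdh1
    "0", "0", "0", "-", "+", "-",   # on OXPHOS
    "0", "-", "0", "0", "-", "0",   # on PPP
    "0", "0", "0", "0", "-", "-"),  # on GLUTAMATE
    nrow = 6, byrow = TRUE,
    dimnames = list(node_order, node_order))
  expect_identical(unclass(als_S), expected)
})

test_that("input sign vector has a single '-' on OXPHOS", {
  expect_identical(unclass(als_Su)[, 1],
                   c(a = "0", k = "0", c = "0", m = "-", p = "0", g = "0"))
  empty <- toy_decoupled()
  expect_true(all(unclass(input_sign_vector(empty)) == "0"))
  two <- input_sign_vector(toy_two_inputs())
  expect_identical(unclass(two)[, 1], c(x = "+", y = "-"))
})

test_that("empty-edge network gives a pure self-degradation matrix", {
  S <- interaction_matrix(toy_decoupled())
  expect_identical(unname(diag(unclass(S))), c("-", "-"))
  expect_true(all(unclass(S)[row(S) != col(S)] == "0"))
})

test_that("the ALS network has exactly three loops, all positive", {
  loops <- enumerate_feedback_loops(als_S)
  expect_length(loops, 3)
  expect_identical(lapply(loops, function(l) l$nodes),
                   list(c("a", "k", "p", "m"),
                        c("c", "k", "p", "g"),
                        c("a", "k", "p", "g", "m")))
  expect_true(all(vapply(loops, function(l) l$overall_sign, numeric(1)) == 1))
  expect_identical(vapply(loops, function(l) l$n_negative, integer(1)),
                   c(2L, 4L, 4L))
})

test_that("removing the PFK3->PPP edge removes every loop", {
  S0 <- unclass(als_S)
  S0["p", "k"] <- "0"
  expect_length(enumerate_feedback_loops(sign_matrix(S0)), 0)
})

test_that("toy networks give the expected loop census", {
  loops <- enumerate_feedback_loops(interaction_matrix(toy_negative_loop()))
  expect_length(loops, 1)
  expect_identical(loops[[1]]$overall_sign, -1)
  expect_identical(loops[[1]]$n_negative, 1L)
})

test_that("candidate multistationarity follows the all-positive-loop rule", {
  expect_true(
    is_candidate_multistationary(enumerate_feedback_loops(als_S))$candidate)
  none <- is_candidate_multistationary(list())
  expect_false(none$candidate)
  expect_match(none$reason, "no loops")
  neg <- is_candidate_multistationary(
    enumerate_feedback_loops(interaction_matrix(toy_negative_loop())))
  expect_false(neg$candidate)
  expect_length(neg$negative_loops, 1)
})

test_that("the monotone gauge flips a, k, g and yields the printed pattern", {
  g <- find_monotone_gauge(als_S)
  expect_identical(g$flips,
                   c(a = -1L, k = -1L, c = 1L, m = 1L, p = 1L, g = -1L))
  gauged <- apply_gauge(als_S, g)
  expected <- matrix(c(
    "-", "0", "0", "+", "0", "0",   # on -AMPK
    "+", "-", "+", "0", "0", "0",   # on -PFK3
    "0", "0", "-", "0", "0", "+",   # on APC^Cdh1
    "0", "0", "0", "-", "+", "+",   # on OXPHOS
    "0", "+", "0", "0", "-", "0",   # on PPP
    "0", "0", "0", "0", "+", "-"),  # on -GLUTAMATE
    nrow = 6, byrow = TRUE,
    dimnames = list(node_order, node_order))
  expect_identical(unclass(gauged), expected)
  # off-diagonal Metzler: no '-' anywhere off the diagonal
  off <- row(gauged) != col(gauged)
  expect_false(any(unclass(gauged)[off] == "-"))
})

test_that("brute force confirms the ALS gauge is unique up to global sign", {
  all_gauges <- brute_force_gauges(als_S)
  expect_length(all_gauges, 2)
  canonical <- find_monotone_gauge(als_S)$flips
  expect_true(any(vapply(all_gauges, function(d) all(d == canonical),
                         logical(1))))
  expect_true(any(vapply(all_gauges, function(d) all(d == -canonical),
                         logical(1))))
})

test_that("gauge edge cases: identity gauge and infeasible patterns", {
  expect_identical(
    unname(find_monotone_gauge(interaction_matrix(toy_all_activation()))$flips),
    rep(1L, 3))
  expect_null(find_monotone_gauge(interaction_matrix(toy_negative_loop())))
  expect_length(brute_force_gauges(interaction_matrix(toy_negative_loop())),
                0)
})

test_that("gauge finder agrees with brute force on random graphs", {
  # a gauge exists iff the *undirected* signed support is balanced; the
  # popular "all directed cycles positive" form needs strong connectivity
  # (a signed DAG with an unbalanced undirected triangle has no directed
  # cycle and no gauge), so the equivalence is asserted separately below
  set.seed(1234)
  n_checked <- 0
  for (rep in 1:150) {
    S <- random_sign_pattern(sample(2:5, 1), p = 0.45)
    loops <- enumerate_feedback_loops(S)
    all_pos <- length(loops) == 0 ||
      all(vapply(loops, function(l) l$overall_sign, numeric(1)) == 1)
    bf <- brute_force_gauges(S)
    gauge <- find_monotone_gauge(S)
    expect_identical(!is.null(gauge), length(bf) > 0)
    # gauge exists => every directed cycle is positive (always true)
    if (!is.null(gauge)) {
      expect_true(all_pos)
      expect_true(any(vapply(bf, function(d) all(d == gauge$flips),
                             logical(1))))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("balance: loops positive iff gauge exists (strongly connected)", {
  set.seed(4321)
  n_pos <- 0
  for (rep in 1:150) {
    n <- sample(2:5, 1)
    # random strongly connected pattern: signed Hamiltonian cycle plus
    # random extra signed edges
    m <- matrix("0", n, n)
    perm <- sample(n)
    for (i in seq_len(n)) {
      m[perm[if (i == n) 1 else i + 1], perm[i]] <- sample(c("+", "-"), 1)
    }
    extra <- which(m == "0" & row(m) != col(m))
    for (e in extra) if (runif(1) < 0.3) m[e] <- sample(c("+", "-"), 1)
    diag(m) <- "-"
    S <- sign_matrix(m, letters[1:n], letters[1:n])
    loops <- enumerate_feedback_loops(S)
    all_pos <- all(vapply(loops, function(l) l$overall_sign,
                          numeric(1)) == 1)
    bf <- brute_force_gauges(S)
    expect_identical(all_pos, length(bf) > 0)
    if (all_pos) n_pos <- n_pos + 1
  }
  expect_gt(n_pos, 10)
})

test_that("the ALS structural influence matrix equals the printed one", {
  M <- structural_influence_matrix(als_S)
  pm <- c("+", "+", "-", "-", "-", "+")
  expected <- matrix(nrow = 6, ncol = 6, byrow = TRUE, data = c(
    pm,                                  # on AMPK
    pm,                                  # on PFK3
    ifelse(pm == "+", "-", "+"),         # on APC^Cdh1
    ifelse(pm == "+", "-", "+"),         # on OXPHOS
    ifelse(pm == "+", "-", "+"),         # on PPP
    pm),                                 # on GLUTAMATE
    dimnames = list(node_order, node_order))
  expect_identical(sm_entries(M), expected)
  expect_false(any(unclass(M) == "?"))
  expect_false(attr(M, "structurally_singular"))
})

test_that("a single-node system has influence '+'", {
  S1 <- sign_matrix(matrix("-", 1, 1), "x", "x")
  expect_identical(unclass(structural_influence_matrix(S1))[1, 1], "+")
})

test_that("the Monte-Carlo determinant oracle agrees with the symbolic path", {
  M <- unclass(structural_influence_matrix(als_S))
  o <- influence_sign_oracle(als_S, n_draws = 200, seed = 99)
  expect_identical(o$signs, sm_entries(structural_influence_matrix(als_S)))
  expect_true(all(o$dominant_real))
})

test_that("oracle agrees with the symbolic signs on random patterns", {
  set.seed(77)
  for (rep in 1:15) {
    S <- random_sign_pattern(sample(2:4, 1), p = 0.5)
    M <- unclass(suppressWarnings(structural_influence_matrix(S)))
    o <- suppressWarnings(
      influence_sign_oracle(S, n_draws = 60, seed = 500 + rep,
                            max_attempts = 5000))
    if (length(o$dominant_real) < 20) next  # too few stable draws to judge
    determined <- M %in% c("+", "-", "0")
    expect_identical(o$signs[determined], M[determined])
  }
})

test_that("input-output influence matches the printed vector", {
  io <- input_output_influence(als_S, als_Su)
  expect_identical(unclass(io)[, 1],
                   c(a = "+", k = "+", c = "-", m = "-", p = "-", g = "+"))
  # consistency: minus the OXPHOS column of the influence matrix
  M <- unclass(structural_influence_matrix(als_S))
  flipped <- ifelse(M[, "m"] == "+", "-", ifelse(M[, "m"] == "-", "+", "0"))
  expect_identical(unname(unclass(io)[, 1]), unname(flipped))
})

test_that("input-output influence handles empty and double inputs", {
  dec <- toy_decoupled()
  io0 <- input_output_influence(interaction_matrix(dec),
                                input_sign_vector(dec))
  expect_true(all(unclass(io0) == "0"))
  two <- toy_two_inputs()
  io2 <- input_output_influence(interaction_matrix(two),
                                input_sign_vector(two))
  # u1 (+ on x) raises x; x raises y but u2 (- on y) lowers y: undetermined
  expect_identical(unclass(io2)[, 1], c(x = "+", y = "?"))
})

test_that("dominant eigenvalue is real for magnitudes consistent with S", {
  o <- influence_sign_oracle(als_S, n_draws = 300, seed = 13,
                             require_stable = FALSE)
  expect_true(all(o$dominant_real))
})
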
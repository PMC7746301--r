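# shared fixtures and independent oracles, built in code

# two-node toy: a activates b, b inhibits a -> one negative loop
toy_negative_loop <- function() {
  signed_network(
    c("x", "y"),
    data.frame(from = c("x", "y"), to = c("y", "x"), sign = c(1L, -1L),
               label = c("e1", "e2")),
    input_node = "u")
}

# three-node all-activation cycle -> identity gauge
toy_all_activation <- function() {
  signed_network(
    c("x", "y", "z"),
    data.frame(from = c("x", "y", "z"), to = c("y", "z", "x"),
               sign = c(1L, 1L, 1L), label = c("e1", "e2", "e3")),
    input_node = "u")
}

# two isolated nodes (no edges): decoupled system for zero-influence checks
toy_decoupled <- function() {
  signed_network(c("x", "y"),
                 data.frame(from = character(), to = character(),
                            sign = integer(), label = character()),
                 input_node = "u")
}

# network with two input edges of opposite sign
toy_two_inputs <- function() {
  signed_network(
    c("x", "y"),
    data.frame(from = "x", to = "y", sign = 1L, label = "e1"),
    input_node = "u",
    input_edges = data.frame(target = c("x", "y"), sign = c(1L, -1L),
                             label = c("u1", "u2")))
}

# random sign pattern with '-' diagonal, edge prob p, n nodes
random_sign_pattern <- function(n, p = 0.4) {
  m <- matrix("0", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && stats::runif(1) < p) {
      m[i, j] <- sample(c("+", "-"), 1)
    }
  }
  diag(m) <- "-"
  sign_matrix(m, letters[seq_len(n)], letters[seq_len(n)])
}

# independent oracle: brute force over all 2^n gauges; returns list of all
# flip vectors (as +/-1) whose D S D has no negative off-diagonal entry
brute_force_gauges <- function(S) {
  n <- nrow(S)
  num <- matrix(c(`-` = -1, `0` = 0, `+` = 1)[unclass(S)], n, n)
  diag(num) <- 0
  out <- list()
  for (mask in 0:(2^n - 1)) {
    d <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1, 1)
    g <- diag(d) %*% num %*% diag(d)
    if (all(g >= 0)) out[[length(out) + 1]] <- stats::setNames(d, rownames(S))
  }
  out
}

# bare character matrix of a sign_matrix (class and analysis attributes
# stripped), for exact comparisons
sm_entries <- function(S) {
  matrix(unclass(S), nrow(S), ncol(S), dimnames = dimnames(S))
}

# a fresh copy of the pinned bistable fixture at mid-window mu
fixture_params <- function(mu = reference_mu_mid()) {
  reference_parameterization(mu = mu)
}
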
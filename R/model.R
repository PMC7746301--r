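#' Assemble a full model parameterization
#'
#' Binds a [signed_network()] to concrete dynamics: one response function per
#' edge, a time constant per node, a constant input level u, and the strength
#' multiplier mu on the key PFK3 -> PPP inhibition (edge `h5`), so the
#' effective inhibition is mu * h5(k).  Each agent x_i obeys
#' \deqn{\tau_i \dot x_i + x_i = \sum_{j \to i} r_{ji}(x_j) + \sum_{u \to i} r_u(u)}
#' where every r is a monotone response: production terms minus first-order
#' decay.
#'
#' @param network a `signed_network`; defaults to [als_network()].
#' @param responses named list of [response_function()]s, one per edge label
#'   (internal and input edges).  Activation edges need kind `"activation"`,
#'   inhibition edges kind `"inhibition"` (or `"zero"` for a knockout).
#' @param tau named numeric vector of strictly positive time constants, one
#'   per node.
#' @param u constant exogenous input level (mutant SOD1), >= 0.
#' @param mu strength multiplier >= 0 on edge `h5`; `mu = 1` is the unscaled
#'   model, `mu = 0` the knockout.
#'
#' @return An object of class `model_parameterization`.
#' @export
model_parameterization <- function(network = als_network(), responses, tau,
                                   u = 0, mu = 1) {
  stopifnot(inherits(network, "signed_network"))
  labels <- c(network$edges$label, network$input_edges$label)
  missing <- setdiff(labels, names(responses))
  if (length(missing)) {
    stop("missing response function(s) for edge(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(responses), labels)
  if (length(extra)) {
    stop("response(s) for unknown edge(s): ", paste(extra, collapse = ", "))
  }
  for (lab in labels) {
    fn <- responses[[lab]]
    if (!inherits(fn, "response_function")) {
      stop("responses[['", lab, "']] is not a response_function")
    }
    sgn <- if (lab %in% network$edges$label) {
      network$edges$sign[network$edges$label == lab]
    } else {
      network$input_edges$sign[network$input_edges$label == lab]
    }
    want <- if (sgn > 0) "activation" else "inhibition"
    if (fn$kind != "zero" && fn$kind != want) {
      stop("edge '", lab, "' has sign ", sgn, " but a ", fn$kind,
           " response")
    }
  }
  if (!all(network$nodes %in% names(tau))) {
    stop("tau must name every node; missing: ",
         paste(setdiff(network$nodes, names(tau)), collapse = ", "))
  }
  tau <- tau[network$nodes]
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("all time constants must be strictly positive")
  }
  if (!is.numeric(u) || length(u) != 1 || u < 0) stop("u must be a scalar >= 0")
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0) {
    stop("mu must be a scalar >= 0")
  }
  out <- structure(
    list(network = network, responses = responses[labels], tau = tau,
         u = u, mu = mu),
    class = "model_parameterization"
  )
  out$compiled <- compile_params(out)
  out
}

# flatten the edge/response structure into parallel vectors so the hot
# paths (production, Jacobian) avoid data.frame row access
compile_params <- function(params) {
  net <- params$network
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  ne <- nrow(net$edges); ni <- nrow(net$input_edges)
  labels <- c(net$edges$label, net$input_edges$label)
  fns <- params$responses[labels]
  kindcode <- vapply(fns, function(f)
    switch(f$kind, activation = 1L, inhibition = 2L, zero = 0L),
    integer(1))
  list(
    n = length(net$nodes),
    from = c(idx[net$edges$from], rep(NA_integer_, ni)),
    to = c(idx[net$edges$to], idx[net$input_edges$target]),
    is_input = c(rep(FALSE, ne), rep(TRUE, ni)),
    is_h5 = labels == "h5",
    kind = kindcode,
    num = vapply(fns, function(f) f$numerator, numeric(1)),
    sat = vapply(fns, function(f) f$saturation, numeric(1)),
    hill = vapply(fns, function(f) f$hill, numeric(1))
  )
}

# fast production over a bare numeric state (no validation, no names)
prod_fast <- function(x, cp, u, mu) {
  xs <- ifelse(cp$is_input, u, x[ifelse(cp$is_input, 1L, cp$from)])
  xn <- xs^cp$hill
  v <- numeric(length(xs))
  act <- cp$kind == 1L; inh <- cp$kind == 2L
  v[act] <- cp$num[act] * xn[act] / (1 + cp$sat[act] * xn[act])
  v[inh] <- cp$num[inh] / (1 + cp$sat[inh] * xn[inh])
  v[cp$is_h5] <- v[cp$is_h5] * mu
  out <- numeric(cp$n)
  for (e in seq_along(v)) out[cp$to[e]] <- out[cp$to[e]] + v[e]
  out
}

# fast tau*J + analytic derivative assembly: returns P'(x) - I
prodjac_fast <- function(x, cp, u, mu) {
  A <- diag(-1, cp$n)
  for (e in seq_along(cp$kind)) {
    if (cp$is_input[e] || cp$kind[e] == 0L) next
    xs <- x[cp$from[e]]
    n <- cp$hill[e]
    d <- if (xs > 0) {
      xn <- xs^n
      den <- (1 + cp$sat[e] * xn)^2
      if (cp$kind[e] == 1L) cp$num[e] * n * xs^(n - 1) / den
      else -cp$num[e] * cp$sat[e] * n * xs^(n - 1) / den
    } else {
      if (n == 1) (if (cp$kind[e] == 1L) cp$num[e]
                   else -cp$num[e] * cp$sat[e]) else 0
    }
    if (cp$is_h5[e]) d <- d * mu
    A[cp$to[e], cp$from[e]] <- A[cp$to[e], cp$from[e]] + d
  }
  A
}

#' @export
print.model_parameterization <- function(x, ...) {
  cat("model_parameterization over", length(x$network$nodes), "nodes\n")
  cat("  u =", x$u, " mu =", x$mu, "\n")
  cat("  tau:", paste(sprintf("%s=%.4g", names(x$tau), x$tau),
                      collapse = " "), "\n")
  for (lab in names(x$responses)) {
    fn <- x$responses[[lab]]
    cat(sprintf("  %-3s %s(%g, %g, n=%g)\n", lab, substr(fn$kind, 1, 3),
                fn$numerator, fn$saturation, fn$hill))
  }
  invisible(x)
}

check_state <- function(state, params) {
  n <- length(params$network$nodes)
  if (length(state) != n) {
    stop("state has length ", length(state), ", expected ", n)
  }
  if (any(state < 0)) stop("state must lie in the nonnegative orthant")
  stats::setNames(as.numeric(state), params$network$nodes)
}

# effective multiplier for an edge: mu on h5, 1 elsewhere
edge_scale <- function(params, label) {
  if (identical(label, "h5")) params$mu else 1
}

# total production (all incoming response terms, including input edges)
# per node; equilibria solve production(x) == x
model_production <- function(state, params) {
  state <- check_state(state, params)
  net <- params$network
  prod <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    prod[e$to] <- prod[e$to] +
      edge_scale(params, e$label) *
      eval_response(state[[e$from]], params$responses[[e$label]])
  }
  for (i in seq_len(nrow(net$input_edges))) {
    e <- net$input_edges[i, ]
    prod[e$target] <- prod[e$target] +
      eval_response(params$u, params$responses[[e$label]])
  }
  prod
}

#' Right-hand side of the loop-system ODEs
#'
#' Returns \eqn{\dot x} with \eqn{\dot x_i = (\mathrm{production}_i(x) - x_i)/\tau_i}.
#' For the ALS network the OXPHOS equation collects h7(u) + h1(g) + f2(p),
#' the PFK3 equation f1(a) + h4(c), and the PPP equation mu * h5(k).
#'
#' @param state numeric state vector in node order (a, k, c, m, p, g for the
#'   ALS network), nonnegative.
#' @param params a [model_parameterization()].
#' @return named numeric vector of rates.
#' @export
model_rhs <- function(state, params) {
  state <- check_state(state, params)
  (model_production(state, params) - state) / params$tau
}

#' Analytic Jacobian of the loop system
#'
#' The (i, j) entry is \eqn{\partial \dot x_i / \partial x_j}: a strictly
#' negative self-decay \eqn{-1/\tau_i} on the diagonal plus the derivative of
#' every response on an edge j -> i.  Because Hill responses are strictly
#' monotone on the open positive orthant, the off-diagonal sign pattern is
#' state-independent there and equals the network's edge signs.
#'
#' @inheritParams model_rhs
#' @return 6 x 6 (generally n x n) matrix with dimnames in node order.
#' @export
model_jacobian <- function(state, params) {
  state <- check_state(state, params)
  net <- params$network
  n <- length(net$nodes)
  J <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    J[e$to, e$from] <- J[e$to, e$from] +
      edge_scale(params, e$label) *
      response_deriv(state[[e$from]], params$responses[[e$label]])
  }
  diag(J) <- diag(J) - 1
  J / params$tau
}

#' Default unit-parameter responses for the ALS network
#'
#' Convenience constructor: every edge gets a Hill response with unit scales
#' and a common exponent.  With `hill = 1` and u = 0 these are the simplest
#' smooth saturating kinetics; they are handy for exercising the machinery
#' but are NOT steep enough to be bistable (see
#' [reference_parameterization()] for the pinned bistable instance).
#'
#' @param network a `signed_network`.
#' @param hill common Hill exponent.
#' @param tau common time constant.
#' @param u input level.
#' @param mu strength multiplier on `h5`.
#' @return a `model_parameterization`.
#' @export
unit_parameterization <- function(network = als_network(), hill = 1,
                                  tau = 1, u = 0, mu = 1) {
  labels <- c(network$edges$label, network$input_edges$label)
  signs <- c(network$edges$sign, network$input_edges$sign)
  responses <- stats::setNames(lapply(seq_along(labels), function(i) {
    response_function(if (signs[i] > 0) "activation" else "inhibition",
                      numerator = 1, saturation = 1, hill = hill)
  }), labels)
  model_parameterization(network, responses,
                         tau = stats::setNames(rep(tau, length(network$nodes)),
                                               network$nodes),
                         u = u, mu = mu)
}
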
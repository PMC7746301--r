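# Dormand-Prince 5(4) adaptive step; no stiff machinery needed: the loop
# system is smooth with O(1) time constants and bounded production.
dp45_step <- function(f, t, x, h) {
  k1 <- f(t, x)
  k2 <- f(t + h / 5, x + h * k1 / 5)
  k3 <- f(t + 3 * h / 10, x + h * (3 * k1 + 9 * k2) / 40)
  k4 <- f(t + 4 * h / 5, x + h * (44 * k1 / 45 - 56 * k2 / 15 + 32 * k3 / 9))
  k5 <- f(t + 8 * h / 9,
          x + h * (19372 * k1 / 6561 - 25360 * k2 / 2187 +
                     64448 * k3 / 6561 - 212 * k4 / 729))
  k6 <- f(t + h,
          x + h * (9017 * k1 / 3168 - 355 * k2 / 33 + 46732 * k3 / 5247 +
                     49 * k4 / 176 - 5103 * k5 / 18656))
  x5 <- x + h * (35 * k1 / 384 + 500 * k3 / 1113 + 125 * k4 / 192 -
                   2187 * k5 / 6784 + 11 * k6 / 84)
  k7 <- f(t + h, x5)
  x4 <- x + h * (5179 * k1 / 57600 + 7571 * k3 / 16695 + 393 * k4 / 640 -
                   92097 * k5 / 339200 + 187 * k7 / 2100 + k7 / 40)
  list(x = x5, err = max(abs(x5 - x4)))
}

#' Simulate the loop system
#'
#' Integrates the ODEs with an adaptive Dormand-Prince 5(4) scheme.  The
#' dynamics map the nonnegative orthant into itself (production is
#' nonnegative and decay linear), so any tiny negative numerical excursion
#' is clamped to 0.
#'
#' @param params a [model_parameterization()].
#' @param x0 nonnegative initial state in node order.
#' @param t_end final time.
#' @param n_out number of output times (uniform grid including 0 and
#'   `t_end`).
#' @param rtol,atol relative/absolute local error tolerances.
#' @return object of class `trajectory`: list with `time`, `states`
#'   (matrix, one row per output time), `params`, `x0` and
#'   `final_residual` (max abs rhs at the final state).
#' @export
simulate <- function(params, x0, t_end = 100, n_out = 201,
                     rtol = 1e-8, atol = 1e-10) {
  x0 <- check_state(x0, params)
  cp <- params$compiled %||% compile_params(params)
  tau <- unname(params$tau)
  f <- function(t, x) {
    x <- pmax(x, 0)
    (prod_fast(x, cp, params$u, params$mu) - x) / tau
  }
  t_out <- seq(0, t_end, length.out = n_out)
  states <- matrix(NA_real_, n_out, length(x0),
                   dimnames = list(NULL, names(x0)))
  states[1, ] <- x0
  t <- 0; x <- x0; h <- min(0.1, t_end / 10); iout <- 2L
  while (t < t_end && iout <= n_out) {
    h <- min(h, t_end - t)
    st <- dp45_step(f, t, x, h)
    tol <- atol + rtol * max(abs(x), abs(st$x))
    if (st$err <= tol || h < 1e-12) {
      t_new <- t + h
      # dense-ish output: linear interpolation within an accepted step
      while (iout <= n_out && t_out[iout] <= t_new + 1e-14) {
        w <- if (h > 0) (t_out[iout] - t) / h else 0
        states[iout, ] <- pmax((1 - w) * x + w * st$x, 0)
        iout <- iout + 1L
      }
      t <- t_new
      x <- pmax(st$x, 0)
    }
    fac <- if (st$err > 0) 0.9 * (tol / st$err)^0.2 else 5
    h <- h * min(5, max(0.2, fac))
  }
  structure(list(time = t_out, states = states, params = params, x0 = x0,
                 final_residual = max(abs(model_rhs(states[n_out, ],
                                                    params)))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("trajectory: t in [0, %g], %d output points\n",
              max(x$time), n))
  cat("final state:", paste(sprintf("%s=%.5g", colnames(x$states),
                                    x$states[n, ]), collapse = " "), "\n")
  cat(sprintf("final residual (max |rhs|): %.3g\n", x$final_residual))
  invisible(x)
}

# integrate until the rhs is numerically stationary (or t_max); returns the
# final state
simulate_to_steady <- function(params, x0, t_max = 2000, tol = 1e-10,
                               chunk = 25) {
  x <- check_state(x0, params)
  t <- 0
  while (t < t_max) {
    tr <- simulate(params, x, t_end = chunk, n_out = 2)
    x <- tr$states[2, ]
    t <- t + chunk
    if (max(abs(model_rhs(x, params))) < tol) break
  }
  x
}

# upper bound per variable on any equilibrium: sum of suprema of incoming
# production terms, + 10% headroom (decay is linear so x_i <= production_i)
equilibrium_box <- function(params) {
  net <- params$network
  ub <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    ub[e$to] <- ub[e$to] +
      edge_scale(params, e$label) * response_sup(params$responses[[e$label]])
  }
  for (i in seq_len(nrow(net$input_edges))) {
    e <- net$input_edges[i, ]
    ub[e$target] <- ub[e$target] + response_sup(params$responses[[e$label]])
  }
  ub * 1.1 + 1e-3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# damped Newton on G(x) = production(x) - x (tau-free: same roots as rhs);
# returns the named root or NULL
newton_equilibrium <- function(params, x0, max_iter = 80, tol = 1e-12) {
  cp <- params$compiled %||% compile_params(params)
  x <- pmax(unname(as.numeric(x0)), 0)
  for (it in seq_len(max_iter)) {
    g <- prod_fast(x, cp, params$u, params$mu) - x
    if (max(abs(g)) < tol) break
    A <- prodjac_fast(x, cp, params$u, params$mu)  # P'(x) - I
    dx <- tryCatch(solve(A, -g), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    lam <- 1
    repeat {
      xn <- pmax(x + lam * dx, 0)
      gn <- prod_fast(xn, cp, params$u, params$mu) - xn
      if (max(abs(gn)) < max(abs(g)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (max(abs(prod_fast(x, cp, params$u, params$mu) - x)) < 1e-10) {
    stats::setNames(x, params$network$nodes)
  } else NULL
}

make_equilibrium <- function(params, state, stability_margin = 1e-8) {
  J <- model_jacobian(state, params)
  ev <- eigen(J, only.values = TRUE)$values
  dom <- ev[which.max(Re(ev))]
  stable <- all(Re(ev) < -stability_margin)
  marginal <- !stable && all(Re(ev) < stability_margin)
  structure(list(state = state, eigenvalues = ev,
                 dominant_eigenvalue = dom, stable = stable,
                 marginal = marginal,
                 residual = max(abs(model_rhs(state, params))),
                 label = "unclassified"),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium (%s%s, label: %s)\n",
              if (x$stable) "stable" else "unstable",
              if (isTRUE(x$marginal)) ", marginal" else "", x$label))
  cat(" ", paste(sprintf("%s=%.6g", names(x$state), x$state),
                 collapse = "  "), "\n")
  cat(sprintf("  dominant eigenvalue: %.6g%+.2gi  residual: %.2g\n",
              Re(x$dominant_eigenvalue), Im(x$dominant_eigenvalue),
              x$residual))
  invisible(x)
}

#' Locate all equilibria by multistart Newton search
#'
#' Runs a damped Newton iteration on production(x) - x from (i) `n_starts`
#' uniform random points inside the box that provably contains every
#' equilibrium (each variable is bounded by the sum of suprema of its
#' incoming production terms), plus the box corners 0 and the upper bound,
#' and (ii) the endpoints of long simulations started from those corners.
#' Roots are deduplicated at relative tolerance `dedup_tol` (absolute floor
#' 1e-9) and classified by the Jacobian spectrum.  Deterministic under
#' `seed`.
#'
#' @param params a [model_parameterization()].
#' @param n_starts number of random starting points (>= 1).
#' @param seed RNG seed (local to this call).
#' @param dedup_tol relative per-coordinate deduplication tolerance.
#' @param simulate_starts also refine endpoints of corner simulations.
#' @return list of `equilibrium` objects sorted by the PFK3 (second)
#'   coordinate; empty (with a warning) if no start converged.
#' @export
find_equilibria <- function(params, n_starts = 40, seed = 1,
                            dedup_tol = 1e-6, simulate_starts = TRUE) {
  stopifnot(n_starts >= 1)
  ub <- equilibrium_box(params)
  n <- length(ub)
  starts <- list(rep(0, n), ub)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (i in seq_len(n_starts)) {
    starts[[length(starts) + 1]] <- stats::runif(n) * ub
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (simulate_starts) {
    starts[[length(starts) + 1]] <- simulate_to_steady(params, rep(0, n))
    starts[[length(starts) + 1]] <- simulate_to_steady(params, ub)
  }
  sols <- list()
  for (s in starts) {
    x <- newton_equilibrium(params, s)
    if (is.null(x)) next
    dup <- any(vapply(sols, function(y) {
      all(abs(x - y) <= pmax(dedup_tol * abs(y), 1e-9))
    }, logical(1)))
    if (!dup) sols[[length(sols) + 1]] <- x
  }
  if (!length(sols)) {
    warning("no equilibrium found from any start")
    return(list())
  }
  eqs <- lapply(sols, function(s) make_equilibrium(params, s))
  eqs[order(vapply(eqs, function(e) e$state[[2]], numeric(1)))]
}

#' Label coexisting stable equilibria as healthy or pathological
#'
#' Among coexisting stable equilibria the one with higher OXPHOS (m) is
#' "healthy" and the one with lower m "pathological".  The labelling is then
#' checked against the full qualitative ordering -- healthy has m, p, c
#' higher AND a, k, g lower than pathological -- and both are downgraded to
#' "unclassified" (with a warning) if any of the six orderings fails or the
#' two states tie within tolerance.  A single stable equilibrium is
#' compared, in the same gauge order, against `reference_midpoint` (by
#' default the midpoint of the two stable states of the pinned bistable
#' fixture at mid-window mu); if it is on neither side consistently it stays
#' "unclassified".
#'
#' @param equilibria list of `equilibrium` objects (from
#'   [find_equilibria()]).
#' @param reference_midpoint optional named state used to classify a lone
#'   stable equilibrium; `NULL` computes the fixture midpoint (cached per
#'   session).
#' @param tol tie tolerance on each coordinate.
#' @return the input list with `label` fields filled in.
#' @export
classify_health <- function(equilibria, reference_midpoint = NULL,
                            tol = 1e-6) {
  st <- which(vapply(equilibria, function(e) isTRUE(e$stable), logical(1)))
  if (!length(st)) stop("no stable equilibrium to classify")
  hi <- c("m", "p", "c")  # higher at the healthy state
  lo <- c("a", "k", "g")  # lower at the healthy state
  if (length(st) >= 2) {
    ms <- vapply(st, function(i) equilibria[[i]]$state[["m"]], numeric(1))
    iH <- st[which.max(ms)]; iP <- st[which.min(ms)]
    xH <- equilibria[[iH]]$state; xP <- equilibria[[iP]]$state
    unclassify <- function(eqs) {
      for (i in seq_along(eqs)) eqs[[i]]$label <- "unclassified"
      eqs
    }
    if (max(abs(xH - xP)) < tol) {
      warning("stable equilibria coincide within tolerance; unclassified")
      return(unclassify(equilibria))
    }
    ok <- all(xH[hi] > xP[hi] + tol) && all(xH[lo] < xP[lo] - tol)
    if (!ok) {
      warning("stable equilibria do not satisfy the full healthy/",
              "pathological ordering; unclassified")
      return(unclassify(equilibria))
    }
    equilibria[[iH]]$label <- "healthy"
    equilibria[[iP]]$label <- "pathological"
  } else {
    mid <- if (is.null(reference_midpoint)) fixture_midpoint() else
      reference_midpoint
    x <- equilibria[[st]]$state
    healthy_side <- all(x[hi] > mid[hi]) && all(x[lo] < mid[lo])
    path_side <- all(x[hi] < mid[hi]) && all(x[lo] > mid[lo])
    if (healthy_side && !path_side) equilibria[[st]]$label <- "healthy"
    else if (path_side && !healthy_side) {
      equilibria[[st]]$label <- "pathological"
    }
  }
  equilibria
}

# midpoint of the two stable states of the reference fixture at its
# mid-window mu; computed once per session
fixture_env <- new.env(parent = emptyenv())
fixture_midpoint <- function() {
  if (is.null(fixture_env$midpoint)) {
    params <- reference_parameterization()
    eqs <- find_equilibria(params, n_starts = 40, seed = 1)
    st <- Filter(function(e) e$stable, eqs)
    if (length(st) != 2) stop("reference fixture is not bistable?")
    fixture_env$midpoint <- (st[[1]]$state + st[[2]]$state) / 2
  }
  fixture_env$midpoint
}

#' Numerically verify the structural influence predictions
#'
#' For each node j, adds a persistent additive input `epsilon` to equation
#' j, recomputes the steady state by continuation (warm-started Newton from
#' the unperturbed equilibrium), and compares the sign of every shift
#' `delta x_i` with entry (i, j) of the structural influence matrix.  The
#' exogenous input u is perturbed the same way and compared against
#' [input_output_influence()].  If the continuation leaves the linear
#' neighbourhood (attained shift much larger than the linear prediction
#' from the Jacobian -- a basin escape), epsilon is halved; entries still
#' escaping at the minimal epsilon are marked untestable, never counted as
#' disagreement.
#'
#' @param params a [model_parameterization()].
#' @param equilibrium a stable `equilibrium` of `params`.
#' @param epsilon initial perturbation size.
#' @param min_epsilon smallest epsilon tried before marking untestable.
#' @return list with `table` (data.frame: perturbed, node, predicted,
#'   observed, agree, untestable), `n_agree`, `n_testable`,
#'   `u_signs` (observed signs under the u perturbation) and
#'   `u_predicted`.
#' @export
verify_influence_numerically <- function(params, equilibrium,
                                         epsilon = 1e-3,
                                         min_epsilon = 1e-7) {
  stopifnot(inherits(equilibrium, "equilibrium"), isTRUE(equilibrium$stable))
  net <- params$network
  nodes <- net$nodes
  S <- interaction_matrix(net)
  M <- unclass(structural_influence_matrix(S))
  io <- unclass(input_output_influence(S, input_sign_vector(net)))[, 1]
  x0 <- equilibrium$state
  n <- length(nodes)
  # linear response: (I - P'(x)) shift = eps * e_j, and I - P' = -tau*J
  A <- -(model_jacobian(x0, params) * params$tau)
  rows <- list()

  solve_shift <- function(j, lin_pred, eps) {
    # Newton on production + eps*e_j - x, warm start, with escape check
    repeat {
      root <- newton_perturbed(params, x0, j, eps)
      if (!is.null(root)) {
        shift <- root - x0
        lin <- lin_pred * eps
        if (sqrt(sum(shift^2)) <= 5 * sqrt(sum(lin^2)) + 1e-12) {
          return(list(shift = shift, eps = eps, untestable = FALSE))
        }
      }
      eps <- eps / 2
      if (eps < min_epsilon) {
        return(list(shift = NULL, eps = eps, untestable = TRUE))
      }
    }
  }

  for (j in seq_len(n)) {
    ej <- stats::setNames(numeric(n), nodes); ej[j] <- 1
    lin_pred <- solve(A, ej)
    res <- solve_shift(j, lin_pred, epsilon)
    for (i in seq_len(n)) {
      pred <- M[i, j]
      if (res$untestable) {
        rows[[length(rows) + 1]] <- data.frame(
          perturbed = nodes[j], node = nodes[i], predicted = pred,
          observed = NA_character_, agree = NA, untestable = TRUE)
        next
      }
      d <- res$shift[i]
      # Newton residual 1e-12 leaves O(1e-10) noise in the root; shifts
      # below that resolve no sign.  A sub-resolution shift confirms a
      # predicted '0' but cannot test a predicted sign: mark untestable.
      thresh <- 1e-9
      obs <- if (abs(d) <= thresh) "0" else if (d > 0) "+" else "-"
      untestable <- obs == "0" && pred != "0"
      rows[[length(rows) + 1]] <- data.frame(
        perturbed = nodes[j], node = nodes[i], predicted = pred,
        observed = obs, agree = if (untestable) NA else
          identical(obs, pred),
        untestable = untestable)
    }
  }
  tab <- do.call(rbind, rows)

  # u perturbation: bump the input level and re-solve
  eps <- epsilon
  u_obs <- rep(NA_character_, n)
  repeat {
    p2 <- params; p2$u <- params$u + eps
    root <- newton_equilibrium(p2, x0)
    if (!is.null(root)) {
      shift <- root - x0
      bu <- stats::setNames(numeric(n), nodes)
      for (i in seq_len(nrow(net$input_edges))) {
        e <- net$input_edges[i, ]
        bu[e$target] <- bu[e$target] +
          response_deriv(params$u, params$responses[[e$label]])
      }
      lin <- solve(A, bu * eps)
      if (sqrt(sum(shift^2)) <= 5 * sqrt(sum(lin^2)) + 1e-12) {
        u_obs <- ifelse(abs(shift) <= 1e-9, "0",
                        ifelse(shift > 0, "+", "-"))
        break
      }
    }
    eps <- eps / 2
    if (eps < min_epsilon) break
  }
  io_pred <- io
  u_untestable <- is.na(u_obs) | (u_obs == "0" & io_pred != "0")

  list(table = tab,
       n_agree = sum(tab$agree, na.rm = TRUE),
       n_testable = sum(!tab$untestable),
       u_signs = stats::setNames(u_obs, nodes),
       u_predicted = io_pred,
       u_untestable = stats::setNames(u_untestable, nodes))
}

# Newton for the system production(x) + eps * e_j - x = 0, warm started
newton_perturbed <- function(params, x0, j, eps, max_iter = 60) {
  cp <- params$compiled %||% compile_params(params)
  x <- unname(as.numeric(x0))
  gfun <- function(x) {
    g <- prod_fast(x, cp, params$u, params$mu) - x
    g[j] <- g[j] + eps
    g
  }
  for (it in seq_len(max_iter)) {
    g <- gfun(x)
    if (max(abs(g)) < 1e-12) break
    A <- prodjac_fast(x, cp, params$u, params$mu)
    dx <- tryCatch(solve(A, -g), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    lam <- 1
    repeat {
      xn <- pmax(x + lam * dx, 0)
      if (max(abs(gfun(xn))) < max(abs(g)) || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (max(abs(gfun(x))) < 1e-10) {
    stats::setNames(x, params$network$nodes)
  } else NULL
}
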
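#' Knock out a single interaction
#'
#' Returns a parameterization with the named edge's response replaced by the
#' zero function and the edge removed from the network (so structural
#' re-analysis sees the reduced graph).  Knocking out `h5` is the same as
#' setting mu = 0, and both are applied for consistency.
#'
#' @param params a [model_parameterization()].
#' @param edge_label label of an internal edge (e.g. `"h5"`, `"f1"`).
#' @return a new `model_parameterization` on the reduced network.
#' @export
knockout_edge <- function(params, edge_label) {
  net <- params$network
  if (!edge_label %in% net$edges$label) {
    stop("unknown edge '", edge_label, "'; valid edges: ",
         paste(net$edges$label, collapse = ", "))
  }
  net2 <- drop_edge(net, edge_label)
  responses <- params$responses[c(net2$edges$label, net2$input_edges$label)]
  mu <- if (identical(edge_label, "h5")) 0 else params$mu
  model_parameterization(net2, responses, params$tau, u = params$u, mu = mu)
}

#' Closed-form steady state of the h5 knockout
#'
#' When the PFK3 -> PPP inhibition is absent (mu = 0 or edge `h5` knocked
#' out) the graph is loop-free and the unique equilibrium follows by direct
#' substitution: p = 0, g = h3(0), c = h2(g), m = h7(u) + h1(g) + f2(0),
#' a = h6(m), k = f1(a) + h4(c).  Responses missing from a reduced network
#' contribute 0.
#'
#' @param params a [model_parameterization()] of the ALS network (or a
#'   reduction of it) with mu = 0 or `h5` removed.
#' @return an `equilibrium` object (stability computed from the Jacobian).
#' @export
knockout_equilibrium_closed_form <- function(params) {
  net <- params$network
  has_h5 <- "h5" %in% net$edges$label
  if (has_h5 && params$mu != 0) {
    stop("closed form requires mu = 0 (or edge h5 knocked out); mu = ",
         params$mu)
  }
  r <- function(lab, x) {
    fn <- params$responses[[lab]]
    if (is.null(fn)) 0 else eval_response(x, fn)
  }
  p <- 0
  g <- r("h3", p)
  c_ <- r("h2", g)
  m <- r("h7", params$u) + r("h1", g) + r("f2", p)
  a <- r("h6", m)
  k <- r("f1", a) + r("h4", c_)
  state <- stats::setNames(c(a, k, c_, m, p, g), net$nodes)
  eq <- make_equilibrium(params, state)
  if (eq$residual > 1e-8) {
    stop("closed-form state does not satisfy the equations (residual ",
         format(eq$residual), "); is this the ALS topology?")
  }
  eq
}

#' Sweep the scale mu of the PFK3 -> PPP response
#'
#' Note on orientation: mu multiplies the whole response mu * h5(k), so a
#' *larger* mu feeds PPP more at any given PFK3 level.  By the structural
#' influence matrix (a positive persistent input on the PPP equation lowers
#' PFK3 at any stable equilibrium), steady-state PFK3 is *nonincreasing* in
#' mu along every stable branch, and the unique low-mu equilibrium is the
#' high-PFK3 pathological one.  "Strengthening the PFK3 -> PPP suppression"
#' therefore corresponds to *decreasing* mu on this axis.
#'
#' For each mu on the grid, finds the full equilibrium set by warm-started
#' continuation from the previous grid point plus periodic cold multistarts,
#' assembles solution branches by nearest-neighbour matching, locates fold
#' points by bisection on the stable-equilibrium count, and reports the
#' bistable window (mu values with >= 2 stable equilibria).
#'
#' @param params a [model_parameterization()]; its own `mu` is ignored.
#' @param mu_grid increasing grid of mu values (default 200 log-spaced
#'   points on \[1e-2, 1e2\]).
#' @param seed RNG seed for the multistarts.
#' @param n_starts cold multistart count per grid point.
#' @param fold_rel_tol relative mu resolution of the bisection.
#' @return object of class `bifurcation_diagram`: list with `parameter`,
#'   `grid`, `points` (data.frame: mu, branch, the six state columns,
#'   stable), `counts` (data.frame: mu, n_total, n_stable), `folds`
#'   (numeric, bisected fold locations), `window` (range with >= 2 stable,
#'   or NULL), `boundary_fold_flag` (TRUE if the window touches the grid
#'   boundary, leaving a fold outside the swept range).
#' @export
sweep_mu <- function(params, mu_grid = NULL, seed = 1, n_starts = 25,
                     fold_rel_tol = 1e-3) {
  if (is.null(mu_grid)) {
    mu_grid <- exp(seq(log(1e-2), log(1e2), length.out = 200))
  }
  if (is.unsorted(mu_grid, strictly = TRUE)) {
    stop("mu_grid must be strictly increasing")
  }
  eq_at <- function(mu, warm = list(), starts = n_starts, sd = seed) {
    p <- params; p$mu <- mu
    eqs <- find_equilibria(p, n_starts = starts, seed = sd,
                           simulate_starts = FALSE)
    # warm starts: continue every previous solution
    for (w in warm) {
      x <- newton_equilibrium(p, w)
      if (is.null(x)) next
      dup <- any(vapply(eqs, function(e) {
        all(abs(x - e$state) <= pmax(1e-6 * abs(e$state), 1e-9))
      }, logical(1)))
      if (!dup) eqs[[length(eqs) + 1]] <- make_equilibrium(p, x)
    }
    eqs[order(vapply(eqs, function(e) e$state[[2]], numeric(1)))]
  }

  nodes <- params$network$nodes
  all_pts <- list()
  counts <- data.frame(mu = mu_grid, n_total = NA_integer_,
                       n_stable = NA_integer_)
  prev_states <- list()
  branch_of_prev <- integer(0)
  next_branch <- 1L
  for (gi in seq_along(mu_grid)) {
    mu <- mu_grid[gi]
    eqs <- eq_at(mu, warm = prev_states, sd = seed + gi)
    counts$n_total[gi] <- length(eqs)
    counts$n_stable[gi] <- sum(vapply(eqs, function(e) e$stable, logical(1)))
    # nearest-neighbour branch assignment against the previous grid point
    branch <- integer(length(eqs))
    used <- logical(length(prev_states))
    for (ei in seq_along(eqs)) {
      if (length(prev_states)) {
        d <- vapply(prev_states, function(s) {
          max(abs(eqs[[ei]]$state - s) / (abs(s) + 1e-6))
        }, numeric(1))
        d[used] <- Inf
        bi <- which.min(d)
        if (is.finite(d[bi]) && d[bi] < 0.5) {
          branch[ei] <- branch_of_prev[bi]
          used[bi] <- TRUE
          next
        }
      }
      branch[ei] <- next_branch
      next_branch <- next_branch + 1L
    }
    for (ei in seq_along(eqs)) {
      all_pts[[length(all_pts) + 1]] <- data.frame(
        mu = mu, branch = branch[ei],
        as.list(eqs[[ei]]$state),
        stable = eqs[[ei]]$stable)
    }
    prev_states <- lapply(eqs, function(e) e$state)
    branch_of_prev <- branch
  }
  points <- do.call(rbind, all_pts)

  # folds: bisection on the stable-count change between adjacent grid points
  folds <- numeric(0)
  stable_count_at <- function(mu, warm) {
    eqs <- eq_at(mu, warm = warm, sd = seed)
    sum(vapply(eqs, function(e) e$stable, logical(1)))
  }
  for (gi in seq_len(length(mu_grid) - 1)) {
    c1 <- counts$n_stable[gi]; c2 <- counts$n_stable[gi + 1]
    if (c1 == c2) next
    lo <- mu_grid[gi]; hi <- mu_grid[gi + 1]
    warm <- lapply(split(points[points$mu %in% c(lo, hi), nodes],
                         seq_len(sum(points$mu %in% c(lo, hi)))),
                   function(r) unlist(r))
    while ((hi - lo) / lo > fold_rel_tol) {
      mid <- sqrt(lo * hi)
      if (stable_count_at(mid, warm) == c1) lo <- mid else hi <- mid
    }
    folds <- c(folds, sqrt(lo * hi))
  }

  bist <- counts$mu[counts$n_stable >= 2]
  window <- if (length(bist)) range(bist) else NULL
  boundary <- !is.null(window) &&
    (window[1] <= mu_grid[1] || window[2] >= mu_grid[length(mu_grid)])
  structure(list(parameter = "mu", grid = mu_grid, points = points,
                 counts = counts, folds = sort(folds), window = window,
                 boundary_fold_flag = boundary,
                 fold_rel_tol = fold_rel_tol),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation_diagram over %s: %d grid points in [%.3g, %.3g]\n",
              x$parameter, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  stable-count pattern: %s\n",
              paste(rle(x$counts$n_stable)$values, collapse = " -> ")))
  if (length(x$folds)) {
    cat("  folds near:", paste(signif(x$folds, 4), collapse = ", "), "\n")
  }
  if (!is.null(x$window)) {
    cat(sprintf("  bistable window: [%.4g, %.4g]%s\n", x$window[1],
                x$window[2],
                if (x$boundary_fold_flag) " (touches grid boundary!)" else ""))
  } else cat("  no bistable window in the swept range\n")
  invisible(x)
}

#' Hysteresis run: sweep mu up then down through the bistable window
#'
#' At every step the system is integrated to steady state, warm-started
#' from the state attained at the previous step, so the trajectory tracks a
#' stable branch until it disappears at a fold and then jumps.  Inside a
#' bistable window the up-sweep and the down-sweep settle on different
#' branches (path dependence); outside they coincide.
#'
#' @param params a [model_parameterization()]; its `mu` is overridden.
#' @param mu_path numeric vector of mu values, typically up-then-down
#'   (e.g. `c(grid, rev(grid))`).
#' @param x0 initial state for the first step (default: closed-form-like
#'   low state obtained by simulating from the origin).
#' @return data.frame with `step`, `mu`, `direction` and the attained
#'   steady states (one column per node).
#' @export
hysteresis_run <- function(params, mu_path, x0 = NULL) {
  nodes <- params$network$nodes
  p <- params; p$mu <- mu_path[1]
  x <- if (is.null(x0)) simulate_to_steady(p, rep(0, length(nodes))) else
    check_state(x0, params)
  dirs <- c("start", ifelse(diff(mu_path) >= 0, "up", "down"))
  out <- vector("list", length(mu_path))
  for (i in seq_along(mu_path)) {
    p$mu <- mu_path[i]
    x <- simulate_to_steady(p, x)
    x <- newton_equilibrium(p, x)  # polish
    if (is.null(x)) stop("steady state lost at mu = ", mu_path[i])
    out[[i]] <- data.frame(step = i, mu = mu_path[i], direction = dirs[i],
                           as.list(x))
  }
  do.call(rbind, out)
}
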
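#' Parameter ranges for random model instances
#'
#' The study this package implements states no kinetic parameter values, so
#' synthetic parameterizations are drawn from order-unity log-uniform ranges
#' (keeping the solver well-conditioned) with Hill exponents from a small
#' steepness set -- steepness being the known lever for bistability in Hill
#' networks.
#'
#' @param scale_range log-uniform range for every numerator and saturation
#'   scale (alpha, beta, gamma, delta).
#' @param tau_range log-uniform range for the time constants.
#' @param hill_set finite choice set for the Hill exponent (one draw per
#'   edge).
#' @param u_range uniform range for the input level.
#' @return object of class `parameter_ranges`.
#' @export
parameter_ranges <- function(scale_range = c(0.25, 4),
                             tau_range = c(0.5, 2),
                             hill_set = c(2, 4),
                             u_range = c(0, 2)) {
  chk <- function(r, nm, pos = TRUE) {
    if (length(r) != 2 || r[1] > r[2] || (pos && r[1] <= 0)) {
      stop(nm, " must be an ordered ", if (pos) "positive " else "",
           "range")
    }
  }
  chk(scale_range, "scale_range"); chk(tau_range, "tau_range")
  if (length(u_range) != 2 || u_range[1] > u_range[2] || u_range[1] < 0) {
    stop("u_range must be an ordered nonnegative range")
  }
  if (!length(hill_set) || any(hill_set <= 0)) {
    stop("hill_set must be positive")
  }
  structure(list(scale_range = scale_range, tau_range = tau_range,
                 hill_set = sort(hill_set), u_range = u_range),
            class = "parameter_ranges")
}

ranges_hash <- function(ranges) {
  # cheap stable provenance token: the ranges serialized to a string
  paste0("ranges(",
         paste(unlist(ranges, use.names = TRUE), collapse = ","), ")")
}

#' Draw a random model parameterization
#'
#' Deterministic under `seed`: each edge (in label order f1, f2, h1..h7)
#' receives independent scale draws and a Hill exponent from the choice
#' set, then the six time constants and the input level are drawn.  The
#' seed and a hash of the ranges are attached as provenance.
#'
#' @param ranges a [parameter_ranges()].
#' @param seed integer seed.
#' @param network the network to parameterize (default [als_network()]).
#' @return a `model_parameterization` with attributes `seed` and
#'   `ranges_hash`.
#' @export
sample_parameterization <- function(ranges = parameter_ranges(), seed,
                                    network = als_network()) {
  stopifnot(inherits(ranges, "parameter_ranges"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lu <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  labels <- sort(c(network$edges$label, network$input_edges$label))
  signs <- stats::setNames(c(network$edges$sign, network$input_edges$sign),
                           c(network$edges$label, network$input_edges$label))
  responses <- stats::setNames(lapply(labels, function(lab) {
    num <- lu(ranges$scale_range)
    sat <- lu(ranges$scale_range)
    n <- if (length(ranges$hill_set) == 1) ranges$hill_set else
      sample(ranges$hill_set, 1)
    response_function(if (signs[[lab]] > 0) "activation" else "inhibition",
                      numerator = num, saturation = sat, hill = n)
  }), labels)
  tau <- stats::setNames(
    vapply(network$nodes, function(nd) lu(ranges$tau_range), numeric(1)),
    network$nodes)
  u <- stats::runif(1, ranges$u_range[1], ranges$u_range[2])
  out <- model_parameterization(network, responses, tau, u = u, mu = 1)
  attr(out, "seed") <- seed
  attr(out, "ranges_hash") <- ranges_hash(ranges)
  out
}

#' Search random parameterizations for bistable regimes
#'
#' Draws `n_samples` instances (instance i uses seed `seed + i`, so every
#' hit is independently reproducible), runs a coarse mu sweep on each, and
#' retains instances showing >= 2 stable equilibria at some mu.
#'
#' @param ranges a [parameter_ranges()].
#' @param n_samples number of instances to draw (>= 1).
#' @param seed base seed.
#' @param mu_grid coarse mu grid for the screen (default 17 log-spaced
#'   points on \[1e-2, 1e2\]).
#' @param n_starts multistarts per (instance, mu) during the screen.
#' @param max_hits optional early stop: return once this many hits are
#'   collected (instances are screened in seed order, so the hits returned
#'   are a deterministic prefix of the full run).
#' @return list with `hits` (list of `list(params, seed, window)`),
#'   `n_samples` (number actually screened), `hit_rate`.
#' @export
search_bistable <- function(ranges = parameter_ranges(), n_samples = 100,
                            seed = 1, mu_grid = NULL, n_starts = 20,
                            max_hits = Inf) {
  stopifnot(n_samples >= 1)
  if (is.null(mu_grid)) {
    mu_grid <- exp(seq(log(1e-2), log(1e2), length.out = 17))
  }
  hits <- list()
  for (i in seq_len(n_samples)) {
    s <- seed + i
    params <- sample_parameterization(ranges, seed = s)
    bist_mu <- numeric(0)
    prev <- list()
    for (mu in mu_grid) {
      p <- params; p$mu <- mu
      eqs <- find_equilibria(p, n_starts = n_starts, seed = s,
                             simulate_starts = FALSE)
      for (w in prev) {
        x <- newton_equilibrium(p, w)
        if (is.null(x)) next
        dup <- any(vapply(eqs, function(e) {
          all(abs(x - e$state) <= pmax(1e-6 * abs(e$state), 1e-9))
        }, logical(1)))
        if (!dup) eqs[[length(eqs) + 1]] <- make_equilibrium(p, x)
      }
      prev <- lapply(eqs, function(e) e$state)
      if (sum(vapply(eqs, function(e) e$stable, logical(1))) >= 2) {
        bist_mu <- c(bist_mu, mu)
      }
    }
    if (length(bist_mu)) {
      hits[[length(hits) + 1]] <- list(params = params, seed = s,
                                       window = range(bist_mu))
      if (length(hits) >= max_hits) {
        return(list(hits = hits, n_samples = i, hit_rate = length(hits) / i))
      }
    }
  }
  list(hits = hits, n_samples = n_samples,
       hit_rate = length(hits) / n_samples)
}

#' The pinned bistable reference parameterization
#'
#' The study behind this package publishes no kinetic parameters, so the
#' package ships one frozen bistable instance standing in for the
#' (unstated) parameters of the published bifurcation diagram.  It was
#' found by `search_bistable(parameter_ranges(), seed = 1000, ...)` --
#' instance seed 1010 -- and its values are pinned here as literals
#' (never regenerated at load time).  Its mu sweep shows the
#' 1 -> 3 -> 1 equilibrium pattern; `mu` defaults to the middle of the
#' bistable window.
#'
#' @param mu strength multiplier (default: mid-window value
#'   `reference_mu_mid()`).
#' @return a `model_parameterization`.
#' @export
reference_parameterization <- function(mu = reference_mu_mid()) {
  rf <- function(kind, num, sat, n) {
    response_function(kind, numerator = num, saturation = sat, hill = n)
  }
  responses <- list() # filled by fixture literals below
  vals <- reference_fixture_values()
  responses <- stats::setNames(lapply(names(vals$responses), function(lab) {
    v <- vals$responses[[lab]]
    rf(v$kind, v$numerator, v$saturation, v$hill)
  }), names(vals$responses))
  model_parameterization(als_network(), responses, tau = vals$tau,
                         u = vals$u, mu = mu)
}

#' Mid-window mu of the reference fixture
#'
#' Geometric midpoint of the bistable window pinned at fixture-creation
#' time.
#' @return scalar mu.
#' @export
reference_mu_mid <- function() {
  w <- reference_fixture_values()$window
  sqrt(w[1] * w[2])
}

# Pinned literals of the reference fixture: the draw of
# sample_parameterization(parameter_ranges(), seed = 1015), found bistable
# by search_bistable(seed = 1000, n_samples = 30) and characterized by an
# 80-point log sweep of mu over [1e-2, 1e2] (folds bisected near 7.27 and
# 28.2; window endpoints below are the outermost grid-certified bistable
# mu values).  Values are literals on purpose: the fixture must never
# silently drift if the sampler changes.
reference_fixture_values <- function() {
  list(
    seed = 1015L,
    search_base_seed = 1000L,
    responses = list(
      f1 = list(kind = "activation", numerator = 2.4428173245579048,
                saturation = 0.28710380169300859, hill = 2),
      f2 = list(kind = "activation", numerator = 0.59913015287273419,
                saturation = 0.31057735697152089, hill = 2),
      h1 = list(kind = "inhibition", numerator = 0.2661547600777453,
                saturation = 0.27952039425502034, hill = 2),
      h2 = list(kind = "inhibition", numerator = 1.1136361515231541,
                saturation = 0.93474813913309096, hill = 2),
      h3 = list(kind = "inhibition", numerator = 1.0903673249719974,
                saturation = 2.9037340759288917, hill = 2),
      h4 = list(kind = "inhibition", numerator = 1.0370783369700045,
                saturation = 1.4154491113802696, hill = 4),
      h5 = list(kind = "inhibition", numerator = 1.17445021350016,
                saturation = 2.2666676420585938, hill = 2),
      h6 = list(kind = "inhibition", numerator = 2.7516686589957158,
                saturation = 1.3378325158524917, hill = 2),
      h7 = list(kind = "inhibition", numerator = 0.34875810553405245,
                saturation = 1.2697397082231983, hill = 2)
    ),
    tau = stats::setNames(
      c(0.7192122489641839, 1.1822245105802753, 0.55374508233306297,
        0.68833501040258593, 0.87045637621043337, 0.78722541413718106),
      node_order),
    u = 1.0712066125124693,
    window = c(7.693, 27.74)
  )
}
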
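#' Write a model specification file
#'
#' Serializes a [model_parameterization()] to a documented JSON schema:
#' top-level fields `nodes`, `display`, `edges` (objects with `from`, `to`,
#' `sign`, `label`, `response`), `input` (object with `node`, `edges`),
#' `tau`, `u`, `mu`.  Responses are objects with `kind`, `numerator`,
#' `saturation`, `hill`.
#'
#' @param params a `model_parameterization`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(params, path) {
  net <- params$network
  resp_json <- function(fn) {
    list(kind = fn$kind, numerator = fn$numerator,
         saturation = fn$saturation, hill = fn$hill)
  }
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, ]
    list(from = e$from, to = e$to, sign = e$sign, label = e$label,
         response = resp_json(params$responses[[e$label]]))
  })
  input_edges <- lapply(seq_len(nrow(net$input_edges)), function(i) {
    e <- net$input_edges[i, ]
    list(target = e$target, sign = e$sign, label = e$label,
         response = resp_json(params$responses[[e$label]]))
  })
  obj <- list(nodes = net$nodes,
              display = as.list(net$display),
              edges = edges,
              input = list(node = net$input_node, edges = input_edges),
              tau = as.list(params$tau),
              u = params$u, mu = params$mu)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model specification file
#'
#' Reads and validates the JSON schema written by [write_model_spec()].
#' A missing `mu` defaults to 1 (with a message); validation failures name
#' the offending field.
#'
#' @param path path to a model-spec JSON file.
#' @return a `model_parameterization`.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(x, field, where) {
    if (is.null(x)) stop("model spec is missing '", field, "' in ", where)
    x
  }
  nodes <- unlist(need(obj$nodes, "nodes", "the top level"))
  display <- if (!is.null(obj$display)) unlist(obj$display) else NULL
  parse_resp <- function(r, lab) {
    kind <- need(r$kind, "kind", paste0("response of edge ", lab))
    if (kind == "zero") return(response_function("zero"))
    response_function(kind,
                      numerator = need(r$numerator, "numerator",
                                       paste0("edge ", lab)),
                      saturation = need(r$saturation, "saturation",
                                        paste0("edge ", lab)),
                      hill = need(r$hill, "hill", paste0("edge ", lab)))
  }
  edf <- do.call(rbind, lapply(obj$edges, function(e) {
    data.frame(from = need(e$from, "from", "an edge"),
               to = need(e$to, "to", "an edge"),
               sign = as.integer(need(e$sign, "sign", "an edge")),
               label = need(e$label, "label", "an edge"))
  }))
  input <- need(obj$input, "input", "the top level")
  idf <- do.call(rbind, lapply(input$edges, function(e) {
    data.frame(target = need(e$target, "target", "an input edge"),
               sign = as.integer(need(e$sign, "sign", "an input edge")),
               label = need(e$label, "label", "an input edge"))
  }))
  if (is.null(idf)) {
    idf <- data.frame(target = character(), sign = integer(),
                      label = character())
  }
  net <- signed_network(nodes, edf, input_node = need(input$node, "node",
                                                      "input"),
                        input_edges = idf, display = display)
  responses <- c(
    stats::setNames(lapply(obj$edges, function(e)
      parse_resp(e$response, e$label)),
      vapply(obj$edges, function(e) e$label, character(1))),
    stats::setNames(lapply(input$edges, function(e)
      parse_resp(e$response, e$label)),
      vapply(input$edges, function(e) e$label, character(1)))
  )
  tau <- unlist(need(obj$tau, "tau", "the top level"))
  mu <- obj$mu
  if (is.null(mu)) {
    message("model spec omits mu; defaulting to 1")
    mu <- 1
  }
  model_parameterization(net, responses, tau,
                         u = need(obj$u, "u", "the top level"), mu = mu)
}

sign_matrix_to_json <- function(S) {
  list(rows = rownames(S), cols = colnames(S),
       entries = apply(unclass(S), 1, paste, collapse = ""))
}

#' Run the full built-in analysis and assert every printed claim
#'
#' One call reproduces the package's complete qualitative account of the
#' ALS loop model and turns each structural claim into an assertion:
#' the interaction and input sign matrices, the three positive loops and
#' candidate multistationarity, the monotone gauge and the gauged Metzler
#' pattern, the structural influence matrix (no '?' entries) and the
#' input-output influence vector, the h5-knockout single equilibrium
#' matching the closed form, the reference fixture's 1 -> 3 -> 1 mu sweep
#' with hysteresis, and the numerical influence verification at the
#' fixture's healthy equilibrium.  Any failed claim stops with an itemized
#' message.
#'
#' @param output_dir directory for the JSON report and CSV tables (created
#'   if missing); `NULL` writes nothing.
#' @param seed seed for every stochastic step.
#' @param mu_grid optional mu grid for the sweep (default: 60 log-spaced
#'   points on \[1e-2, 1e2\]; coarser than the interactive default to keep
#'   a reproduction run short).
#' @return an `analysis_report` list, invisibly.
#' @export
reproduce_paper <- function(output_dir = NULL, seed = 1, mu_grid = NULL) {
  failures <- character(0)
  claim <- function(ok, what) {
    if (!isTRUE(ok)) failures <<- c(failures, what)
    ok
  }
  net <- als_network()
  S <- interaction_matrix(net)
  S_u <- input_sign_vector(net)
  claim(identical(unclass(S)["k", ], c(a = "+", k = "-", c = "-", m = "0",
                                       p = "0", g = "0")),
        "interaction matrix row PFK3")
  claim(identical(unclass(S)["m", ], c(a = "0", k = "0", c = "0", m = "-",
                                       p = "+", g = "-")),
        "interaction matrix row OXPHOS")
  claim(identical(unclass(S_u)[, 1], c(a = "0", k = "0", c = "0", m = "-",
                                       p = "0", g = "0")),
        "input sign vector")
  loops <- enumerate_feedback_loops(S)
  claim(length(loops) == 3 &&
          all(vapply(loops, function(l) l$overall_sign, numeric(1)) == 1),
        "three positive loops")
  cand <- is_candidate_multistationary(loops)
  claim(cand$candidate, "candidate multistationarity")
  gauge <- find_monotone_gauge(S)
  claim(!is.null(gauge) &&
          identical(gauge$flips,
                    c(a = -1L, k = -1L, c = 1L, m = 1L, p = 1L, g = -1L)),
        "monotone gauge flips {a, k, g}")
  M <- structural_influence_matrix(S)
  claim(!any(unclass(M) == "?"), "influence matrix fully signed")
  io <- input_output_influence(S, S_u)
  claim(identical(unclass(io)[, 1], c(a = "+", k = "+", c = "-", m = "-",
                                      p = "-", g = "+")),
        "input-output influence (+,+,-,-,-,+)")

  params <- reference_parameterization()
  ko <- knockout_edge(params, "h5")
  ko_eqs <- find_equilibria(ko, n_starts = 30, seed = seed)
  cf <- knockout_equilibrium_closed_form(ko)
  claim(length(ko_eqs) == 1 && ko_eqs[[1]]$stable,
        "knockout: single stable equilibrium")
  claim(length(ko_eqs) == 1 &&
          max(abs(ko_eqs[[1]]$state - cf$state)) < 1e-8,
        "knockout equilibrium matches closed form")
  claim(length(enumerate_feedback_loops(interaction_matrix(ko$network)))
        == 0, "knockout: no loops")

  eqs <- find_equilibria(params, n_starts = 40, seed = seed)
  n_stable <- sum(vapply(eqs, function(e) e$stable, logical(1)))
  claim(length(eqs) == 3 && n_stable == 2,
        "fixture: 2 stable + 1 unstable at mid-window mu")
  eqs <- classify_health(eqs)
  labels <- vapply(eqs, function(e) e$label, character(1))
  claim(all(c("healthy", "pathological") %in% labels),
        "fixture: healthy and pathological labels")

  if (is.null(mu_grid)) {
    mu_grid <- exp(seq(log(1e-2), log(1e2), length.out = 60))
  }
  diagram <- sweep_mu(params, mu_grid, seed = seed)
  pat <- rle(diagram$counts$n_total)$values
  claim(identical(as.integer(pat), c(1L, 3L, 1L)),
        "mu sweep shows 1 -> 3 -> 1")
  claim(identical(as.integer(rle(diagram$counts$n_stable)$values),
                  c(1L, 2L, 1L)),
        "stable count shows 1 -> 2 -> 1")
  claim(length(diagram$folds) == 2, "two folds")
  w <- diagram$window
  up <- mu_grid[mu_grid >= w[1] / 2 & mu_grid <= 2 * w[2]]
  hys <- hysteresis_run(params, c(up, rev(up)))
  nu <- length(up)
  # certified-bistable points must show path dependence; points outside
  # the fold bracket have a unique equilibrium and must agree
  inside <- up >= w[1] & up <= w[2]
  outside <- up < min(diagram$folds) | up > max(diagram$folds)
  k_up <- hys$k[seq_len(nu)]
  k_dn <- rev(hys$k[nu + seq_len(nu)])
  claim(any(abs(k_up[inside] - k_dn[inside]) > 1e-3),
        "hysteresis inside the window")
  claim(all(abs(k_up[outside] - k_dn[outside]) < 1e-5),
        "up/down agreement outside the fold bracket")

  healthy <- eqs[[which(labels == "healthy")[1]]]
  ver <- verify_influence_numerically(params, healthy)
  claim(ver$n_agree == ver$n_testable && ver$n_testable > 0,
        "numerical influence verification agrees on all testable entries")
  claim(identical(unname(ver$u_signs), unname(unclass(io)[, 1])),
        "u-perturbation signs match input-output influence")

  if (length(failures)) {
    stop("claim check failed:\n  - ", paste(failures, collapse = "\n  - "))
  }

  report <- list(
    tool = paste0("loopstate ",
                  as.character(utils::packageVersion("loopstate"))),
    seed = seed,
    model_spec_hash = ranges_hash(list(fixture =
      unlist(reference_fixture_values(), use.names = TRUE))),
    interaction_matrix = sign_matrix_to_json(S),
    input_sign_vector = sign_matrix_to_json(S_u),
    loops = lapply(loops, function(l) list(
      nodes = l$nodes, overall_sign = l$overall_sign,
      n_negative = l$n_negative)),
    candidate_multistationary = cand$candidate,
    gauge = as.list(gauge$flips),
    gauged_matrix = sign_matrix_to_json(apply_gauge(S, gauge)),
    influence_matrix = sign_matrix_to_json(M),
    input_output_influence = sign_matrix_to_json(io),
    knockout = list(n_equilibria = length(ko_eqs),
                    closed_form = as.list(cf$state)),
    fixture = list(mu = params$mu,
                   n_equilibria = length(eqs), n_stable = n_stable,
                   labels = labels,
                   states = lapply(eqs, function(e) as.list(e$state))),
    sweep = list(pattern = pat, folds = diagram$folds,
                 window = diagram$window),
    influence_verification = list(n_agree = ver$n_agree,
                                  n_testable = ver$n_testable,
                                  u_signs = as.list(ver$u_signs))
  )
  class(report) <- "analysis_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(diagram$points,
                     file.path(output_dir, "bifurcation_diagram.csv"),
                     row.names = FALSE)
    utils::write.csv(hys, file.path(output_dir, "hysteresis.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (", x$tool, ", seed ", x$seed, ")\n", sep = "")
  cat("  loops:", length(x$loops),
      "| candidate multistationary:", x$candidate_multistationary, "\n")
  cat("  knockout equilibria:", x$knockout$n_equilibria, "\n")
  cat("  fixture equilibria:", x$fixture$n_equilibria,
      "(", x$fixture$n_stable, "stable )\n")
  cat("  sweep pattern:", paste(x$sweep$pattern, collapse = " -> "),
      "| folds:", paste(signif(x$sweep$folds, 4), collapse = ", "), "\n")
  cat("  influence verification:", x$influence_verification$n_agree, "/",
      x$influence_verification$n_testable, "entries agree\n")
  invisible(x)
}
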
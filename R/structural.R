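#' Sign matrices over the alphabet {+, -, 0, ?}
#'
#' Thin wrapper around a character matrix with node-label dimnames.  `?`
#' marks an influence whose sign depends on parameter magnitudes; it never
#' appears in an interaction matrix.
#'
#' @param entries character matrix over `c("+", "-", "0", "?")`.
#' @param row_labels,col_labels label vectors (defaults: dimnames of
#'   `entries`).
#' @return object of class `sign_matrix`.
#' @export
sign_matrix <- function(entries, row_labels = rownames(entries),
                        col_labels = colnames(entries)) {
  entries <- as.matrix(entries)
  if (!all(entries %in% c("+", "-", "0", "?"))) {
    stop("sign matrix entries must be one of + - 0 ?")
  }
  dimnames(entries) <- list(row_labels, col_labels)
  structure(entries, class = c("sign_matrix", "matrix"))
}

#' @export
print.sign_matrix <- function(x, display = node_display, ...) {
  m <- unclass(x)
  rn <- rownames(m); cn <- colnames(m)
  if (!is.null(display)) {
    rn <- ifelse(rn %in% names(display), display[rn], rn)
    cn <- ifelse(cn %in% names(display), display[cn], cn)
  }
  dimnames(m) <- list(paste("on", rn), cn)
  print(m, quote = FALSE)
  invisible(x)
}

sign_char <- function(s) c(`-1` = "-", `0` = "0", `1` = "+")[as.character(s)]
sign_num <- function(ch) c(`-` = -1, `0` = 0, `+` = 1)[ch]

#' Interaction matrix S of a signed network
#'
#' Entry (i, j) is the sign of the direct effect of agent j on agent i: the
#' sign pattern of the system Jacobian.  The diagonal is all `-`
#' (first-order self-degradation); off-diagonal entries are the edge signs.
#'
#' @param network a [signed_network()].
#' @return a `sign_matrix` in the network's node order.
#' @export
interaction_matrix <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  n <- length(network$nodes)
  S <- matrix("0", n, n, dimnames = list(network$nodes, network$nodes))
  diag(S) <- "-"
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    S[e$to, e$from] <- sign_char(e$sign)
  }
  sign_matrix(S)
}

#' Signed input vector S_u
#'
#' Column of signs of the direct effect of the exogenous input on each
#' equation: for the ALS network a single `-` on OXPHOS.
#'
#' @param network a [signed_network()].
#' @return a one-column `sign_matrix`.
#' @export
input_sign_vector <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  v <- matrix("0", length(network$nodes), 1,
              dimnames = list(network$nodes, network$input_node))
  for (i in seq_len(nrow(network$input_edges))) {
    e <- network$input_edges[i, ]
    v[e$target, 1] <- sign_char(e$sign)
  }
  sign_matrix(v)
}

#' Enumerate simple feedback loops of a sign matrix
#'
#' Finds every simple directed cycle of length >= 2 in the off-diagonal
#' support of `S` (self-degradation diagonal loops are excluded) and
#' classifies each by the product of its edge signs.  A loop is positive iff
#' it contains an even number of inhibitory edges.  Cycles are canonicalised
#' by rotating to the lexicographically smallest starting node and the list
#' is sorted by length, then lexicographically.
#'
#' @param S a square `sign_matrix` (entry (i, j): effect of j on i).
#' @return list of `feedback_loop` objects with fields `nodes`,
#'   `edge_signs`, `overall_sign`, `n_negative`.
#' @export
enumerate_feedback_loops <- function(S) {
  stopifnot(inherits(S, "sign_matrix"), nrow(S) == ncol(S))
  nodes <- rownames(S)
  n <- length(nodes)
  # adjacency: edge j -> i iff S[i, j] != 0, i != j
  num <- matrix(sign_num(unclass(S)), n, n)
  adj <- lapply(seq_len(n), function(j) which(num[, j] != 0 & seq_len(n) != j))
  loops <- list()
  # DFS from each start; only visit nodes with index >= start (each cycle
  # found exactly once, anchored at its smallest-index node)
  path <- integer(0)
  visit <- function(v, start) {
    path[[length(path) + 1L]] <<- v
    for (w in adj[[v]]) {
      if (w == start && length(path) >= 2) {
        loops[[length(loops) + 1L]] <<- path
      } else if (w > start && !(w %in% path)) {
        visit(w, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) visit(s, s)
  out <- lapply(loops, function(idx) {
    # canonical rotation: start at the lexicographically smallest label
    lab <- nodes[idx]
    rot <- which.min(rank(lab, ties.method = "first"))
    if (rot > 1) idx <- c(idx[rot:length(idx)], idx[seq_len(rot - 1)])
    signs <- vapply(seq_along(idx), function(i) {
      from <- idx[i]; to <- idx[if (i == length(idx)) 1L else i + 1L]
      num[to, from]
    }, numeric(1))
    structure(list(nodes = nodes[idx], edge_signs = signs,
                   overall_sign = prod(signs),
                   n_negative = sum(signs < 0)),
              class = "feedback_loop")
  })
  ord <- order(vapply(out, function(l) length(l$nodes), integer(1)),
               vapply(out, function(l) paste(l$nodes, collapse = ""),
                      character(1)))
  out[ord]
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(sprintf("loop %s (%s, %d inhibitory edge%s)\n",
              paste(c(x$nodes, x$nodes[1]), collapse = "-"),
              if (x$overall_sign > 0) "positive" else "negative",
              x$n_negative, if (x$n_negative == 1) "" else "s"))
  invisible(x)
}

#' Candidate multistationarity test
#'
#' A system whose signed graph contains feedback loops that are all positive
#' is a candidate multistationary system: the sign structure permits -- but
#' does not by itself prove -- coexistence of multiple equilibria.  No loops
#' at all means a single equilibrium, hence not a candidate.
#'
#' @param loops output of [enumerate_feedback_loops()].
#' @return list with `candidate` (logical), `reason`, and `negative_loops`.
#' @export
is_candidate_multistationary <- function(loops) {
  if (!length(loops)) {
    return(list(candidate = FALSE, reason = "no loops",
                negative_loops = list()))
  }
  neg <- Filter(function(l) l$overall_sign < 0, loops)
  if (length(neg)) {
    return(list(candidate = FALSE,
                reason = sprintf("%d negative loop(s) present", length(neg)),
                negative_loops = neg))
  }
  list(candidate = TRUE,
       reason = sprintf("all %d loops positive", length(loops)),
       negative_loops = list())
}

#' Find a monotone gauge (variable sign flips giving a Metzler pattern)
#'
#' Searches for a diagonal +/-1 matrix D such that D S D has no negative
#' off-diagonal entry (a Metzler pattern), which certifies that the system
#' is monotone with respect to the orthant order induced by the flips.  The
#' gauge is found by 2-colouring the signed undirected support graph; it
#' exists iff every undirected signed constraint set is consistent, which
#' for a strongly connected pattern is equivalent to all directed cycles
#' being positive.  D and -D are equivalent; the canonical form fixes
#' flip = +1 on the last node in [node_order] present (node `m` for the ALS
#' network) -- more precisely on the first node of the first connected
#' component with an unflipped choice, then normalised so that node `m` (if
#' present) has flip +1.
#'
#' @param S a square `sign_matrix` with `-` diagonal.
#' @return object of class `gauge` (named +/-1 vector in `$flips`), or
#'   `NULL` if no gauge exists.
#' @export
find_monotone_gauge <- function(S) {
  stopifnot(inherits(S, "sign_matrix"), nrow(S) == ncol(S))
  nodes <- rownames(S)
  n <- length(nodes)
  num <- matrix(sign_num(unclass(S)), n, n)
  diag(num) <- 0
  # undirected constraint: flip_i * flip_j = sign of every edge between i, j;
  # conflicting parallel/antiparallel edges make the gauge infeasible
  con <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- num[i, j]
    if (s != 0) {
      if (con[i, j] != 0 && con[i, j] != s) return(NULL)
      con[i, j] <- s; con[j, i] <- s
    }
  }
  flips <- rep(NA_integer_, n)
  for (root in seq_len(n)) {
    if (!is.na(flips[root])) next
    flips[root] <- 1L
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(con[v, ] != 0)) {
        want <- flips[v] * con[v, w]
        if (is.na(flips[w])) {
          flips[w] <- want
          queue <- c(queue, w)
        } else if (flips[w] != want) {
          return(NULL)
        }
      }
    }
  }
  flips <- stats::setNames(as.integer(flips), nodes)
  if ("m" %in% nodes && flips[["m"]] < 0) flips <- -flips
  structure(list(flips = flips), class = "gauge")
}

#' @export
print.gauge <- function(x, ...) {
  cat("gauge (D and -D equivalent; canonical: flip(m) = +1):\n")
  cat(" ", paste(sprintf("%s:%s", names(x$flips),
                         ifelse(x$flips > 0, "+", "-")), collapse = "  "),
      "\n")
  invisible(x)
}

#' Apply a gauge to a sign matrix
#'
#' Computes the similarity D S D, which flips the sign of row i and column i
#' for every node with flip -1; diagonal entries are unchanged.
#'
#' @param S a square `sign_matrix`.
#' @param gauge a `gauge` object (or named +/-1 vector).
#' @return the gauged `sign_matrix`.
#' @export
apply_gauge <- function(S, gauge) {
  flips <- if (inherits(gauge, "gauge")) gauge$flips else gauge
  stopifnot(all(rownames(S) %in% names(flips)))
  num <- matrix(sign_num(unclass(S)), nrow(S), ncol(S))
  d <- flips[rownames(S)]
  out <- diag(d) %*% num %*% diag(d)
  sign_matrix(matrix(sign_char(out), nrow(S), ncol(S)),
              rownames(S), colnames(S))
}

# --- symbolic adjoint machinery ------------------------------------------

# all permutations of 1..k as a matrix (rows)
all_perms <- function(k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  r <- 1L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      row <- integer(k)
      row[pos] <- k
      row[-pos] <- sub[i, ]
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

perm_parity <- function(p) {
  # sign of a permutation via cycle counting
  k <- length(p)
  seen <- logical(k)
  sgn <- 1L
  for (i in seq_len(k)) {
    if (seen[i]) next
    j <- i; len <- 0L
    while (!seen[j]) { seen[j] <- TRUE; j <- p[j]; len <- len + 1L }
    if (len %% 2 == 0) sgn <- -sgn
  }
  sgn
}

# structural sign of det(M) for a numeric sign-pattern matrix M whose
# nonzero entries are independent magnitudes: "+", "-", "0" or "?"
symbolic_det_sign <- function(M) {
  k <- nrow(M)
  if (k == 0) return("+")  # empty product convention: det = 1
  perms <- all_perms(k)
  pos <- FALSE; neg <- FALSE
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    term <- perm_parity(p)
    for (i in seq_len(k)) {
      term <- term * M[i, p[i]]
      if (term == 0) break
    }
    if (term > 0) pos <- TRUE else if (term < 0) neg <- TRUE
    if (pos && neg) return("?")
  }
  if (pos) "+" else if (neg) "-" else "0"
}

#' Structural influence matrix: sign of adj(-J) at stable equilibria
#'
#' Entry (i, k) is the parameter-free sign of the steady-state change of
#' variable i under a persistent additive input on equation k, at a stable
#' equilibrium (then det(-J) > 0 and the sign of the response equals the
#' sign of the (i, k) entry of the adjoint of -J).
#'
#' Two symbolic routes are combined.  (1) Each adjoint entry is expanded
#' into signed permutation terms over the sign pattern, treating every
#' nonzero Jacobian entry as an independent magnitude: if all nonzero terms
#' agree the entry is `+` or `-`, if no term survives it is `0`, otherwise
#' it is undetermined *over unconstrained magnitudes*.  (2) Mixed-sign
#' entries may still be determined once the standing stability assumption
#' is imposed: when the pattern admits a monotone gauge D and its
#' off-diagonal support is irreducible, D(-J)D is an irreducible Metzler
#' sign pattern, and for any *stable* such matrix the adjoint is strictly
#' positive; the entry sign is then the gauge product d_i d_k.  The
#' magnitude realizations that make route (1) terms disagree are exactly
#' the ones with a structurally unstable loop gain, which the stability
#' assumption excludes.  Entries determined by route (1) are cross-checked
#' against route (2) wherever both apply (any mismatch is an internal
#' error).  Entries resolved by neither route are reported as `?`.
#'
#' @param S a square `sign_matrix` with `-` diagonal.
#' @return a `sign_matrix` over `{+, -, 0, ?}`; attribute
#'   `structurally_singular` is TRUE when det(-J) is identically zero over
#'   the pattern (flagged with a warning: no stable equilibrium can exist),
#'   and attribute `stability_resolved` is TRUE when route (2) was used for
#'   at least one entry.
#' @export
structural_influence_matrix <- function(S) {
  stopifnot(inherits(S, "sign_matrix"), nrow(S) == ncol(S))
  nodes <- rownames(S)
  n <- length(nodes)
  negJ <- -matrix(sign_num(unclass(S)), n, n)  # sign pattern of -J
  out <- matrix("0", n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      # adj(-J)[i,k] = (-1)^(i+k) * minor of -J without row k, col i
      minor <- negJ[-k, -i, drop = FALSE]
      s <- symbolic_det_sign(minor)
      if (s %in% c("+", "-") && (i + k) %% 2 == 1) {
        s <- if (s == "+") "-" else "+"
      }
      out[i, k] <- s
    }
  }
  det_sign <- symbolic_det_sign(negJ)
  singular <- identical(det_sign, "0")
  if (singular) {
    warning("det(-J) is identically zero over this sign pattern; ",
            "no stable equilibrium exists and the influence signs are ",
            "reported without the stability assumption")
  }
  used_stability <- FALSE
  gauge <- find_monotone_gauge(S)
  if (!singular && !is.null(gauge) && is_irreducible(S)) {
    d <- gauge$flips[nodes]
    short_ch <- matrix(sign_char(outer(d, d)), n, n)  # all-'+' re-gauged
    mismatch <- out %in% c("+", "-") & out != short_ch
    if (any(mismatch)) {
      stop("internal error: expansion-determined influence signs disagree ",
           "with the irreducible-Metzler shortcut")
    }
    if (any(out == "?") || any(out == "0")) {
      # strict positivity of the adjoint also overrides expansion zeros
      used_stability <- any(out != short_ch)
      out[] <- short_ch
    }
  }
  res <- sign_matrix(out)
  attr(res, "structurally_singular") <- singular
  attr(res, "stability_resolved") <- used_stability
  res
}

# strong connectivity of the off-diagonal support (Kosaraju-lite: BFS both
# directions from node 1)
is_irreducible <- function(S) {
  n <- nrow(S)
  if (n == 1) return(TRUE)
  num <- matrix(sign_num(unclass(S)), n, n)
  diag(num) <- 0
  reach <- function(adj) {
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nxt <- which(adj[, v] != 0 & !seen)
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    all(seen)
  }
  reach(num) && reach(t(num))
}

#' Structural input-output influence vector
#'
#' Sign of the steady-state shift of each variable under a persistent
#' increase of the exogenous input u.  The shift solves 0 = J dx + B du, so
#' dx = adj(-J) B du / det(-J): each entry combines the influence-matrix
#' columns of the input's target equations weighted by the input edge signs
#' (for the ALS network: minus the OXPHOS column of the influence matrix).
#'
#' @param S square interaction `sign_matrix`.
#' @param S_u one-column input `sign_matrix` from [input_sign_vector()].
#' @return a one-column `sign_matrix`.
#' @export
input_output_influence <- function(S, S_u) {
  M <- structural_influence_matrix(S)
  nodes <- rownames(S)
  su <- sign_num(unclass(S_u)[, 1])
  out <- character(length(nodes))
  for (i in seq_along(nodes)) {
    terms <- character(0)
    for (t in which(su != 0)) {
      e <- unclass(M)[i, t]
      if (e == "?") { terms <- c(terms, "?"); next }
      v <- sign_num(e) * su[t]
      if (v != 0) terms <- c(terms, sign_char(v))
    }
    out[i] <- if (!length(terms)) "0"
      else if (any(terms == "?")) "?"
      else if (all(terms == "+")) "+"
      else if (all(terms == "-")) "-"
      else "?"
  }
  sign_matrix(matrix(out, ncol = 1),
              row_labels = nodes, col_labels = colnames(S_u))
}

#' Monte-Carlo oracle for influence signs
#'
#' Draws random magnitudes consistent with the sign pattern (log-uniform in
#' `range`), assembles J, and evaluates the bordered determinant
#' det of rbind(cbind(-J, -C_k), cbind(R_i, 0)), which equals adj(-J)[i, k].
#' Used as an independent check of [structural_influence_matrix()]: across
#' draws a structurally signed entry must never change sign.  Because the
#' influence matrix is defined at a stable equilibrium, draws with an
#' unstable J (some eigenvalue real part >= 0) are rejected by default and
#' redrawn, up to `max_attempts`.
#'
#' @param S square `sign_matrix`.
#' @param n_draws number of (accepted) random magnitude assignments.
#' @param seed RNG seed.
#' @param range positive magnitude range for log-uniform draws.
#' @param require_stable reject draws whose J is not Hurwitz.
#' @param max_attempts cap on total draws while rejecting.
#' @return list with `signs` (character matrix: `+`, `-`, `0` if every draw
#'   agreed, `?` if draws disagreed), `dominant_real` (logical per accepted
#'   draw: was the dominant eigenvalue of J real), and `n_attempted`.
#' @export
influence_sign_oracle <- function(S, n_draws = 1000, seed = 1,
                                  range = c(0.1, 10),
                                  require_stable = TRUE,
                                  max_attempts = 100 * n_draws) {
  stopifnot(inherits(S, "sign_matrix"))
  nodes <- rownames(S)
  n <- length(nodes)
  pat <- matrix(sign_num(unclass(S)), n, n)
  set.seed(seed)
  acc <- matrix("0", n, n)
  dominant_real <- logical(0)
  d <- 0L; attempts <- 0L
  while (d < n_draws && attempts < max_attempts) {
    attempts <- attempts + 1L
    mag <- matrix(exp(stats::runif(n * n, log(range[1]), log(range[2]))),
                  n, n)
    J <- pat * mag
    ev <- eigen(J, only.values = TRUE)$values
    if (require_stable && max(Re(ev)) >= 0) next
    d <- d + 1L
    dom <- ev[which.max(Re(ev))]
    dominant_real[d] <- abs(Im(dom)) < 1e-8
    negJ <- -J
    for (i in seq_len(n)) for (k in seq_len(n)) {
      B <- rbind(cbind(negJ, -diag(n)[, k, drop = FALSE]),
                 cbind(t(diag(n)[, i, drop = FALSE]), 0))
      v <- det(B)
      # identically-zero determinants only leave rounding noise, bounded
      # well below 1e-12 times the Hadamard bound of the bordered matrix
      tol <- 1e-12 * prod(pmax(sqrt(rowSums(B^2)), 1))
      s <- if (abs(v) <= tol) "0" else if (v > 0) "+" else "-"
      cur <- acc[i, k]
      acc[i, k] <- if (cur == "0") s
        else if (s == "0" || s == cur) cur
        else "?"
    }
  }
  if (d < n_draws) {
    warning("only ", d, " stable draws accepted in ", attempts,
            " attempts")
  }
  list(signs = matrix(acc, n, n, dimnames = list(nodes, nodes)),
       dominant_real = dominant_real, n_attempted = attempts)
}
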
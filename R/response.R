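#' Construct a Hill-type response function
#'
#' Interactions between agents are modelled with bounded monotone Hill
#' functions: an activation \eqn{f(x) = \alpha x^n / (1 + \beta x^n)} or an
#' inhibition \eqn{h(x) = \gamma / (1 + \delta x^n)}.  The Hill exponent is
#' called `hill` here (the classical symbol p is already taken by the PPP
#' variable).  A third kind, `"zero"`, is the identically-zero response used
#' to represent a knocked-out interaction.
#'
#' @param kind `"activation"`, `"inhibition"` or `"zero"`.
#' @param numerator numerator scale (alpha for activation, gamma for
#'   inhibition); strictly positive.
#' @param saturation saturation scale (beta / delta); strictly positive.
#' @param hill Hill exponent n > 0.  Exponents below 1 have an unbounded
#'   derivative at 0 and are refused unless `allow_shallow = TRUE`.
#' @param allow_shallow allow 0 < n < 1 (one-sided derivative at 0 reported
#'   as 0 so the Jacobian stays finite).
#'
#' @return An object of class `response_function`.
#' @export
response_function <- function(kind = c("activation", "inhibition", "zero"),
                              numerator = 1, saturation = 1, hill = 1,
                              allow_shallow = FALSE) {
  kind <- match.arg(kind)
  if (kind == "zero") {
    return(structure(list(kind = "zero", numerator = 0, saturation = 1,
                          hill = 1),
                     class = "response_function"))
  }
  if (!is.numeric(numerator) || numerator <= 0 ||
      !is.numeric(saturation) || saturation <= 0 ||
      !is.numeric(hill) || hill <= 0) {
    stop("response parameters must be strictly positive")
  }
  if (hill < 1 && !allow_shallow) {
    stop("Hill exponent < 1 gives an unbounded derivative at 0; ",
         "pass allow_shallow = TRUE to accept it")
  }
  structure(list(kind = kind, numerator = numerator,
                 saturation = saturation, hill = hill),
            class = "response_function")
}

#' Hill activation value
#'
#' Evaluates \eqn{f(x) = \alpha x^n / (1 + \beta x^n)}: zero at the origin,
#' strictly increasing, saturating at \eqn{\alpha/\beta}.
#'
#' @param x nonnegative activity (vectorised).
#' @param fn a `response_function` of kind `"activation"`.
#' @return value(s) of the activation function.
#' @export
hill_activation <- function(x, fn) {
  stopifnot(inherits(fn, "response_function"))
  if (fn$kind != "activation") stop("fn is not an activation response")
  if (any(x < 0)) stop("activity must be nonnegative")
  xn <- x^fn$hill
  fn$numerator * xn / (1 + fn$saturation * xn)
}

#' Hill inhibition value
#'
#' Evaluates \eqn{h(x) = \gamma / (1 + \delta x^n)}: equal to gamma at the
#' origin, strictly decreasing, vanishing as x grows.
#'
#' @inheritParams hill_activation
#' @param fn a `response_function` of kind `"inhibition"`.
#' @return value(s) of the inhibition function.
#' @export
hill_inhibition <- function(x, fn) {
  stopifnot(inherits(fn, "response_function"))
  if (fn$kind != "inhibition") stop("fn is not an inhibition response")
  if (any(x < 0)) stop("activity must be nonnegative")
  fn$numerator / (1 + fn$saturation * x^fn$hill)
}

#' Evaluate a response function of any kind
#' @inheritParams hill_activation
#' @param fn a `response_function`.
#' @return value(s).
#' @export
eval_response <- function(x, fn) {
  switch(fn$kind,
         activation = hill_activation(x, fn),
         inhibition = hill_inhibition(x, fn),
         zero = rep(0, length(x)))
}

# derivative of a response wrt its argument; finite one-sided value at 0
response_deriv <- function(x, fn) {
  if (fn$kind == "zero") return(rep(0, length(x)))
  n <- fn$hill
  out <- numeric(length(x))
  pos <- x > 0
  xp <- x[pos]
  if (fn$kind == "activation") {
    den <- (1 + fn$saturation * xp^n)^2
    out[pos] <- fn$numerator * n * xp^(n - 1) / den
    if (any(!pos)) out[!pos] <- if (n == 1) fn$numerator else 0
  } else {
    den <- (1 + fn$saturation * xp^n)^2
    out[pos] <- -fn$numerator * fn$saturation * n * xp^(n - 1) / den
    if (any(!pos)) out[!pos] <- if (n == 1) -fn$numerator * fn$saturation else 0
  }
  out
}

# supremum of a response on [0, Inf): alpha/beta for activation, gamma for
# inhibition.  Used to bound the equilibrium search box.
response_sup <- function(fn) {
  switch(fn$kind,
         activation = fn$numerator / fn$saturation,
         inhibition = fn$numerator,
         zero = 0)
}

#' @export
print.response_function <- function(x, ...) {
  if (x$kind == "zero") {
    cat("response_function: zero (knocked out)\n")
  } else if (x$kind == "activation") {
    cat(sprintf("response_function: f(x) = %g x^%g / (1 + %g x^%g)\n",
                x$numerator, x$hill, x$saturation, x$hill))
  } else {
    cat(sprintf("response_function: h(x) = %g / (1 + %g x^%g)\n",
                x$numerator, x$saturation, x$hill))
  }
  invisible(x)
}
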
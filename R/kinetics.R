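#' Michaelis-Menten parameter bundle
#'
#' @param Vmax Maximal rate (flux units); the plateau of the rate law.
#' @param KM Half-saturation constant (concentration units); the substrate
#'   concentration at which half of `Vmax` is attained.
#' @return An object of class `"mm_kinetics"`.
#' @export
#' @examples
#' mm_kinetics(Vmax = 2, KM = 1)
mm_kinetics <- function(Vmax, KM) {
  if (!is.numeric(Vmax) || length(Vmax) != 1L || !is.finite(Vmax) || Vmax <= 0) {
    stop("Vmax must be a positive finite number", call. = FALSE)
  }
  if (!is.numeric(KM) || length(KM) != 1L || !is.finite(KM) || KM <= 0) {
    stop("KM must be a positive finite number", call. = FALSE)
  }
  structure(list(Vmax = Vmax, KM = KM), class = "mm_kinetics")
}

#' @export
print.mm_kinetics <- function(x, ...) {
  cat(sprintf("<mm_kinetics> Vmax = %g, KM = %g\n", x$Vmax, x$KM))
  invisible(x)
}

check_conc <- function(X, what = "X", strict = FALSE) {
  if (!is.numeric(X) || any(!is.finite(X))) {
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  }
  if (strict && any(X <= 0)) stop(sprintf("%s must be > 0", what), call. = FALSE)
  if (!strict && any(X < 0)) stop(sprintf("%s must be >= 0", what), call. = FALSE)
  invisible(X)
}

#' Irreversible Michaelis-Menten flux
#'
#' `f(X) = Vmax * X / (KM + X)`: zero at `X = 0`, strictly increasing and
#' bounded above by `Vmax`.
#'
#' @param k An [mm_kinetics()] bundle.
#' @param X Substrate concentration(s), non-negative.
#' @return Flux, same length as `X`.
#' @export
mm_flux <- function(k, X) {
  stopifnot(inherits(k, "mm_kinetics"))
  check_conc(X)
  k$Vmax * X / (k$KM + X)
}

#' Derivative of the Michaelis-Menten flux
#'
#' `f'(X) = Vmax * KM / (KM + X)^2`; at `X = 0` this is the initial slope
#' `Vmax / KM`, the quantity that decides the stability of the empty state
#' of an autocatalytic cycle.
#'
#' @inheritParams mm_flux
#' @return Rate per concentration, same length as `X`.
#' @export
mm_derivative <- function(k, X) {
  stopifnot(inherits(k, "mm_kinetics"))
  check_conc(X)
  k$Vmax * k$KM / (k$KM + X)^2
}

#' Saturation level of a Michaelis-Menten reaction
#'
#' The ratio between the flux carried and the maximal flux the expressed
#' enzyme can carry: `S(X) = X / (KM + X)`, in `[0, 1)`.
#'
#' @inheritParams mm_flux
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
saturation <- function(k, X) {
  stopifnot(inherits(k, "mm_kinetics"))
  check_conc(X)
  X / (k$KM + X)
}

#' Elasticity coefficient of a Michaelis-Menten reaction
#'
#' The normalized sensitivity of flux to substrate,
#' `eps = (df/dX) * (X / f)`, which for Michaelis-Menten kinetics equals
#' `KM / (KM + X) = 1 - S(X)`. Stability of a positive steady state of the
#' single-intermediate cycle is equivalent to the branch elasticity
#' exceeding the autocatalytic elasticity there.
#'
#' @param k An [mm_kinetics()] bundle.
#' @param X Substrate concentration(s), strictly positive.
#' @return Dimensionless elasticity in `(0, 1)`.
#' @export
elasticity <- function(k, X) {
  stopifnot(inherits(k, "mm_kinetics"))
  check_conc(X, strict = TRUE)
  k$KM / (k$KM + X)
}

# ---- bisubstrate mechanisms -------------------------------------------

BISUBSTRATE_SCHEMES <- c("ping_pong", "random_order", "ordered_A_first",
                         "ordered_X_first")

#' Bisubstrate kinetic parameter bundle
#'
#' Parameters of an irreversible two-substrate rate law in one of four
#' mechanisms, written for an autocatalytic reaction consuming an external
#' assimilated metabolite `A` and an internal cycle intermediate `X`:
#' \describe{
#'   \item{ping_pong}{Substituted-enzyme mechanism;
#'     `f = Vmax*A*X / (KX*A + KA*X + A*X)`.}
#'   \item{random_order}{Ternary complex, random binding order;
#'     `f = Vmax*A*X / (KiA*KX + KX*A + KA*X + A*X)`. Needs `KiA`.}
#'   \item{ordered_A_first}{Ternary complex, `A` binds first;
#'     `f = Vmax*A*X / (KiA*KX + KX*A + A*X)`. Needs `KiA`.}
#'   \item{ordered_X_first}{Ternary complex, `X` binds first;
#'     `f = Vmax*A*X / (KiX*KA + KA*X + A*X)`. Needs `KiX`.}
#' }
#'
#' @param scheme One of `"ping_pong"`, `"random_order"`,
#'   `"ordered_A_first"`, `"ordered_X_first"`.
#' @param Vmax Maximal rate.
#' @param KA,KX Michaelis constants for `A` and `X`.
#' @param KiA Dissociation constant of `A` (random and A-first ordered
#'   schemes only).
#' @param KiX Dissociation constant of `X` (X-first ordered scheme only).
#' @return An object of class `"bisubstrate_kinetics"`.
#' @export
bisubstrate_kinetics <- function(scheme, Vmax, KA, KX, KiA = NULL, KiX = NULL) {
  scheme <- match.arg(scheme, BISUBSTRATE_SCHEMES)
  for (nm in c("Vmax", "KA", "KX")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a positive finite number", nm), call. = FALSE)
    }
  }
  needs_KiA <- scheme %in% c("random_order", "ordered_A_first")
  needs_KiX <- scheme == "ordered_X_first"
  if (needs_KiA && (is.null(KiA) || KiA <= 0)) {
    stop(sprintf("scheme '%s' requires positive KiA", scheme), call. = FALSE)
  }
  if (!needs_KiA && !is.null(KiA)) {
    stop(sprintf("scheme '%s' does not use KiA", scheme), call. = FALSE)
  }
  if (needs_KiX && (is.null(KiX) || KiX <= 0)) {
    stop(sprintf("scheme '%s' requires positive KiX", scheme), call. = FALSE)
  }
  if (!needs_KiX && !is.null(KiX)) {
    stop(sprintf("scheme '%s' does not use KiX", scheme), call. = FALSE)
  }
  structure(list(scheme = scheme, Vmax = Vmax, KA = KA, KX = KX,
                 KiA = KiA, KiX = KiX),
            class = "bisubstrate_kinetics")
}

#' @export
print.bisubstrate_kinetics <- function(x, ...) {
  extra <- c(if (!is.null(x$KiA)) sprintf("KiA = %g", x$KiA),
             if (!is.null(x$KiX)) sprintf("KiX = %g", x$KiX))
  cat(sprintf("<bisubstrate_kinetics> %s: Vmax = %g, KA = %g, KX = %g%s\n",
              x$scheme, x$Vmax, x$KA, x$KX,
              if (length(extra)) paste0(", ", paste(extra, collapse = ", ")) else ""))
  invisible(x)
}

#' Bisubstrate flux at given substrate concentrations
#'
#' Evaluates the mechanism's full two-substrate rate law (see
#' [bisubstrate_kinetics()] for the formulas).
#'
#' @param b A [bisubstrate_kinetics()] bundle.
#' @param A Assimilated-metabolite concentration, non-negative.
#' @param X Internal-metabolite concentration, non-negative.
#' @return Flux.
#' @export
bisubstrate_flux <- function(b, A, X) {
  stopifnot(inherits(b, "bisubstrate_kinetics"))
  check_conc(A, "A")
  check_conc(X)
  den <- switch(b$scheme,
    ping_pong = b$KX * A + b$KA * X + A * X,
    random_order = b$KiA * b$KX + b$KX * A + b$KA * X + A * X,
    ordered_A_first = b$KiA * b$KX + b$KX * A + A * X,
    ordered_X_first = b$KiX * b$KA + b$KA * X + A * X)
  out <- b$Vmax * A * X / den
  out[A == 0 | X == 0] <- 0
  out
}

#' Apparent Michaelis-Menten constants at fixed assimilated metabolite
#'
#' At a constant concentration `A` of the assimilated metabolite every
#' bisubstrate mechanism collapses exactly to single-substrate
#' Michaelis-Menten form in `X`. The apparent constants are:
#' \describe{
#'   \item{ping_pong}{`Vmax' = Vmax*A/(KA+A)`, `KM' = KX*A/(KA+A)`}
#'   \item{random_order}{`Vmax' = Vmax*A/(KA+A)`, `KM' = KX*(KiA+A)/(KA+A)`}
#'   \item{ordered_A_first}{`Vmax' = Vmax`, `KM' = KX*(KiA+A)/A`}
#'   \item{ordered_X_first}{`Vmax' = Vmax*A/(KA+A)`, `KM' = KiX*KA/(KA+A)`}
#' }
#'
#' @param b A [bisubstrate_kinetics()] bundle.
#' @param A Constant assimilated-metabolite concentration, strictly positive.
#' @return An [mm_kinetics()] bundle with the apparent constants.
#' @export
#' @examples
#' b <- bisubstrate_kinetics("ping_pong", Vmax = 2, KA = 1, KX = 3)
#' apparent_constants(b, A = 1)  # Vmax' = 1, KM' = 1.5
apparent_constants <- function(b, A) {
  stopifnot(inherits(b, "bisubstrate_kinetics"))
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("A must be a positive finite number", call. = FALSE)
  }
  switch(b$scheme,
    ping_pong = mm_kinetics(b$Vmax * A / (b$KA + A), b$KX * A / (b$KA + A)),
    random_order = mm_kinetics(b$Vmax * A / (b$KA + A),
                               b$KX * (b$KiA + A) / (b$KA + A)),
    ordered_A_first = mm_kinetics(b$Vmax, b$KX * (b$KiA + A) / A),
    ordered_X_first = mm_kinetics(b$Vmax * A / (b$KA + A),
                                  b$KiX * b$KA / (b$KA + A)))
}

#' Read kinetic parameter bundles from a JSON config
#'
#' The config is a JSON object (or array of objects) with a `type` tag:
#' `"mm"` entries carry `Vmax` and `KM`; `"bisubstrate"` entries carry
#' `scheme`, `Vmax`, `KA`, `KX` and the scheme-specific `KiA`/`KiX`.
#'
#' @param path Path to a JSON file.
#' @return A single kinetics object, or a named list of them for an array.
#' @export
read_kinetics <- function(path) {
  x <- jsonlite::read_json(path)
  parse1 <- function(e) {
    type <- e$type %||% if (!is.null(e$scheme)) "bisubstrate" else "mm"
    if (type == "mm") {
      mm_kinetics(e$Vmax, e$KM)
    } else {
      bisubstrate_kinetics(e$scheme, e$Vmax, e$KA, e$KX,
                           KiA = e$KiA, KiX = e$KiX)
    }
  }
  if (!is.null(x$type) || !is.null(x$scheme) || !is.null(x$Vmax)) {
    parse1(x)
  } else {
    lapply(x, parse1)
  }
}
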
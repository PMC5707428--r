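# Generalized Lennard-Jones 6-p pair potential and its analytic well geometry.

#' Boltzmann constant in kcal/(mol K)
#'
#' Named constant used to convert temperatures (K) into thermal energies
#' (kcal/mol) throughout the package, e.g. in [dilute_rdf_model()].
#'
#' @format A length-one numeric.
#' @export
kB <- 0.0019872041

#' Lennard-Jones 6-p parameter set
#'
#' Bundles the three physical parameters of the generalized Lennard-Jones
#' pair potential \eqn{V(r) = 4\epsilon((\sigma/r)^p - (\sigma/r)^6)}:
#' the well-depth scale \eqn{\epsilon} (kcal/mol), the zero-crossing
#' distance \eqn{\sigma} (Angstrom) and the repulsion exponent \eqn{p}.
#' `p = 12` recovers the classical 6-12 potential; `p` is treated as a
#' continuous real parameter and must exceed 6 so that the repulsive term
#' dominates at short range.
#'
#' @param epsilon Well depth scale in kcal/mol, `> 0`.
#' @param sigma Zero-crossing distance in Angstrom, `> 0`.
#' @param p Repulsion exponent, dimensionless, `> 6`. Default 12.
#' @return An object of class `"lj_params"`: a named list with elements
#'   `epsilon`, `sigma`, `p`.
#' @examples
#' pars <- lj_params(0.238, 3.405)
#' lj_energy(3.405, pars)  # exactly zero at r = sigma
#' @export
lj_params <- function(epsilon, sigma, p = 12) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(p), length(p) == 1L)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a positive finite number (kcal/mol)")
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive finite number (Angstrom)")
  if (!is.finite(p) || p <= 6)
    stop("'p' must be finite and > 6 (p = 12 is the classical potential)")
  structure(list(epsilon = epsilon, sigma = sigma, p = p),
            class = "lj_params")
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("Lennard-Jones 6-%.4g parameters: epsilon = %.4g kcal/mol, sigma = %.4g A\n",
              x$p, x$epsilon, x$sigma))
  invisible(x)
}

#' Evaluate the Lennard-Jones 6-p potential
#'
#' Computes \eqn{V(r) = 4\epsilon((\sigma/r)^p - (\sigma/r)^6)} at one or
#' more separations. With `truncated = TRUE` the potential is set to exactly
#' zero beyond the cutoff \eqn{r_c = 3\sigma} (a hard truncation with no
#' energy shift, the convention used for the condensed-phase observables).
#'
#' @param r Separation(s) in Angstrom; all must be `> 0`.
#' @param params An [lj_params()] object.
#' @param truncated Logical; apply the hard \eqn{r_c = 3\sigma} cutoff?
#'   Default `FALSE`.
#' @return Numeric vector of energies in kcal/mol, same length as `r`.
#' @examples
#' p <- lj_params(1, 1, p = 12)
#' lj_energy(2^(1/6), p)          # the classical minimum, -epsilon
#' lj_energy(3.5, p, truncated = TRUE)  # beyond 3*sigma: exactly 0
#' @export
lj_energy <- function(r, params, truncated = FALSE) {
  if (!inherits(params, "lj_params")) params <- do.call(lj_params, as.list(params))
  if (!is.numeric(r) || length(r) == 0L || any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be positive finite separations (Angstrom)")
  sr <- params$sigma / r
  v <- 4 * params$epsilon * (sr^params$p - sr^6)
  if (truncated) v[r > 3 * params$sigma] <- 0
  v
}

#' Analytic well geometry of the 6-p potential
#'
#' Location and depth of the potential minimum. Setting the derivative of
#' \eqn{4\epsilon((\sigma/r)^p - (\sigma/r)^6)} to zero gives
#' \eqn{r_{min} = (p/6)^{1/(p-6)}\sigma}; the depth is the (negative)
#' energy there. For `p = 12` this is the familiar
#' \eqn{r_{min} = 2^{1/6}\sigma}, depth \eqn{-\epsilon}. As `p` decreases
#' toward 6 the well moves out toward \eqn{e^{1/6}\sigma} and becomes
#' arbitrarily shallow.
#'
#' @param params An [lj_params()] object.
#' @return Named list with `r_min` (Angstrom) and `depth` (kcal/mol, `< 0`).
#' @export
lj_well <- function(params) {
  if (!inherits(params, "lj_params")) params <- do.call(lj_params, as.list(params))
  r_min <- (params$p / 6)^(1 / (params$p - 6)) * params$sigma
  list(r_min = r_min, depth = lj_energy(r_min, params))
}
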
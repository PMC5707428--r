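# Gaussian curve likelihood with inferred noise scale, uniform box priors,
# and the conditional prior families used by the hierarchical layer.

PARAM_ORDER <- c("epsilon", "sigma", "p", "sigma_n")

#' Uniform box prior specification
#'
#' Componentwise-independent uniform prior over a box, ordered as
#' (epsilon, sigma, p, sigma_n) with `p` present only for the 6-p model.
#'
#' @param lower,upper Named numeric vectors with identical names drawn
#'   from `epsilon`, `sigma`, `p`, `sigma_n`; `lower < upper` componentwise
#'   and the lower bound of `p`, when present, must exceed 6.
#' @return An object of class `"lj_prior"`.
#' @seealso [lj_prior()] for the default calibration boxes.
#' @export
prior_spec <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            !is.null(names(lower)), identical(names(lower), names(upper)))
  nm <- names(lower)
  if (!all(nm %in% PARAM_ORDER)) stop("unknown parameter names in prior")
  ord <- PARAM_ORDER[PARAM_ORDER %in% nm]
  lower <- lower[ord]; upper <- upper[ord]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("prior bounds must be finite with lower < upper componentwise")
  if ("p" %in% ord && lower[["p"]] <= 6)
    stop("lower bound of 'p' must be > 6")
  structure(list(lower = lower, upper = upper, names = ord), class = "lj_prior")
}

#' Default calibration priors
#'
#' The wide uniform boxes used for the two potentials:
#' LJ 6-12 (epsilon, sigma, sigma_n) over
#' \eqn{[0.05, 3] \times [3, 4] \times [10^{-6}, 1]}; LJ 6-p
#' (epsilon, sigma, p, sigma_n) over
#' \eqn{[0.05, 10] \times [3, 4] \times [6.01, 15] \times [10^{-6}, 1]}.
#' The wider epsilon range of the 6-p box accommodates the strong
#' correlation between epsilon and p.
#'
#' @param model `"lj6-12"` or `"lj6-p"`.
#' @return An `"lj_prior"`.
#' @export
lj_prior <- function(model = c("lj6-12", "lj6-p")) {
  model <- match.arg(model)
  if (model == "lj6-12")
    prior_spec(c(epsilon = 0.05, sigma = 3, sigma_n = 1e-6),
               c(epsilon = 3,    sigma = 4, sigma_n = 1))
  else
    prior_spec(c(epsilon = 0.05, sigma = 3, p = 6.01, sigma_n = 1e-6),
               c(epsilon = 10,   sigma = 4, p = 15,   sigma_n = 1))
}

#' @export
print.lj_prior <- function(x, ...) {
  cat("Uniform box prior:\n")
  for (nm in x$names)
    cat(sprintf("  %-8s [%g, %g]\n", nm, x$lower[[nm]], x$upper[[nm]]))
  invisible(x)
}

prior_widths <- function(spec) spec$upper - spec$lower

prior_contains <- function(spec, theta) {
  th <- theta_matrix(theta, spec$names)
  ok <- rep(TRUE, nrow(th))
  for (j in seq_along(spec$names))
    ok <- ok & th[, j] >= spec$lower[j] & th[, j] <= spec$upper[j]
  ok
}

# Coerce a named vector / matrix / lj_params-ish list to a matrix with the
# requested columns, one row per parameter point.
theta_matrix <- function(theta, names) {
  if (is.matrix(theta)) {
    if (is.null(colnames(theta))) {
      if (ncol(theta) != length(names)) stop("theta has wrong dimension")
      colnames(theta) <- names
    }
    return(theta[, names, drop = FALSE])
  }
  if (is.list(theta)) theta <- unlist(theta)
  if (is.null(names(theta))) {
    if (length(theta) != length(names)) stop("theta has wrong length")
    names(theta) <- names
  }
  matrix(theta[names], nrow = 1, dimnames = list(NULL, names))
}

#' Gaussian curve log-likelihood
#'
#' Log density of the observed curve under the i.i.d. Gaussian data model
#' \eqn{d \sim N(f, \sigma_n^2 I)}:
#' \deqn{-\frac{N_d}{2}\log(2\pi\sigma_n^2) - \frac{SSE}{2\sigma_n^2},
#'   \quad SSE = \sum_i (d_i - f_i)^2.}
#' The single noise scale `sigma_n` (same units as the curve) is inferred
#' jointly with the physical parameters; bins are not weighted, so curve
#' features with large residual leverage (e.g. the RDF peak) dominate the
#' sum of squared errors naturally.
#'
#' @param observed Observed curve, or an [lj_dataset()] (its `values` are
#'   used).
#' @param model_curve Model curve of the same length.
#' @param sigma_n Noise scale, `> 0`.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(observed, model_curve, sigma_n) {
  if (inherits(observed, "lj_dataset")) observed <- observed$values
  if (length(observed) != length(model_curve))
    stop(sprintf("curve length mismatch: %d observed vs %d model",
                 length(observed), length(model_curve)))
  if (!is.finite(sigma_n) || sigma_n <= 0) stop("'sigma_n' must be > 0")
  if (any(!is.finite(observed)) || any(!is.finite(model_curve)))
    stop("curves must be finite")
  n <- length(observed)
  sse <- sum((observed - model_curve)^2)
  -n / 2 * log(2 * pi * sigma_n^2) - sse / (2 * sigma_n^2)
}

#' Uniform box log-prior density
#'
#' @param theta Named parameter vector (or matrix, one row per point).
#' @param spec An `"lj_prior"`.
#' @return Log-density: `-sum(log(widths))` inside the box, `-Inf` outside.
#'   Vectorized over rows of `theta`.
#' @export
log_prior_uniform <- function(theta, spec) {
  stopifnot(inherits(spec, "lj_prior"))
  inside <- prior_contains(spec, theta)
  val <- -sum(log(prior_widths(spec)))
  unname(ifelse(inside, val, -Inf))
}

#' Conditional prior family for the hierarchical layer
#'
#' In the hierarchical model the per-dataset physical parameters share a
#' hyper-parameterized conditional prior \eqn{p(\theta | \psi)}. Two
#' families are provided, both factorized over the tied parameters and
#' renormalized over the global box `base`:
#'
#' * `"truncnorm"` (default): independent truncated normals; `psi` holds a
#'   location (`loc_*`, inside the base box) and a scale (`scale_*`,
#'   positive) per tied parameter. Smooth shrinkage toward the
#'   population-level location.
#' * `"uniform"`: a sub-box parameterized per tied parameter by a center
#'   (`center_*`, inside the base box) and half-width (`halfwidth_*`);
#'   the sub-interval is clipped to the base box and renormalized. A
#'   half-width of the full base width recovers the base uniform prior
#'   exactly.
#'
#' The noise scale `sigma_n` is never tied: it keeps its base uniform
#' factor per dataset, since the noise level is condition-specific.
#'
#' @param family `"truncnorm"` or `"uniform"`.
#' @param base An `"lj_prior"`: the global box the family is truncated to.
#' @param tied Names of the parameters governed by `psi`; defaults to the
#'   physical parameters (everything except `sigma_n`).
#' @return An object of class `"lj_prior_family"` with elements `family`,
#'   `base`, `tied`, `psi_names`, and `hyper_box` (an `"lj_prior"`-like
#'   box over `psi`: locations/centers range over the base box, scales and
#'   half-widths over `(10^{-3} w, w)` with `w` the base width).
#' @export
prior_family <- function(family = c("truncnorm", "uniform"), base,
                         tied = setdiff(base$names, "sigma_n")) {
  family <- match.arg(family)
  stopifnot(inherits(base, "lj_prior"), all(tied %in% base$names))
  w <- prior_widths(base)[tied]
  lo <- base$lower[tied]; hi <- base$upper[tied]
  if (family == "truncnorm") {
    psi_lower <- c(lo, 1e-3 * w)
    psi_upper <- c(hi, w)
    psi_names <- c(paste0("loc_", tied), paste0("scale_", tied))
  } else {
    psi_lower <- c(lo, 1e-3 * w)
    psi_upper <- c(hi, w)
    psi_names <- c(paste0("center_", tied), paste0("halfwidth_", tied))
  }
  names(psi_lower) <- names(psi_upper) <- psi_names
  structure(list(family = family, base = base, tied = tied,
                 psi_names = psi_names,
                 hyper_box = list(lower = psi_lower, upper = psi_upper,
                                  names = psi_names)),
            class = "lj_prior_family")
}

psi_split <- function(psi, fam) {
  if (is.null(names(psi))) names(psi) <- fam$psi_names
  k <- length(fam$tied)
  loc <- psi[seq_len(k)]
  scl <- psi[k + seq_len(k)]
  if (any(!is.finite(scl)) || any(scl <= 0))
    stop("inadmissible psi: scales/half-widths must be positive")
  list(loc = unname(loc), scale = unname(scl))
}

#' Conditional log-prior density p(theta | psi)
#'
#' Evaluates the factorized conditional prior of a [prior_family()] at one
#' or more parameter points. Untied parameters (always `sigma_n`)
#' contribute their base uniform factor, so the result is a proper density
#' over the full parameter vector.
#'
#' @param theta Named parameter vector or matrix (rows = points).
#' @param psi Hyper-parameter vector laid out as `family$psi_names`.
#' @param family An `"lj_prior_family"`.
#' @return Log-density, vectorized over rows of `theta`.
#' @export
conditional_log_prior <- function(theta, psi, family) {
  stopifnot(inherits(family, "lj_prior_family"))
  base <- family$base
  th <- theta_matrix(theta, base$names)
  ps <- psi_split(psi, family)
  out <- rep(0, nrow(th))
  # untied parameters keep the base uniform factor
  untied <- setdiff(base$names, family$tied)
  for (nm in untied) {
    x <- th[, nm]
    inside <- x >= base$lower[[nm]] & x <= base$upper[[nm]]
    out <- out + ifelse(inside, -log(base$upper[[nm]] - base$lower[[nm]]), -Inf)
  }
  for (j in seq_along(family$tied)) {
    nm <- family$tied[j]
    x <- th[, nm]
    a <- base$lower[[nm]]; b <- base$upper[[nm]]
    if (family$family == "truncnorm") {
      m <- ps$loc[j]; s <- ps$scale[j]
      z <- stats::pnorm(b, m, s) - stats::pnorm(a, m, s)
      ld <- stats::dnorm(x, m, s, log = TRUE) - log(z)
      ld[x < a | x > b] <- -Inf
    } else {
      lo <- max(a, ps$loc[j] - ps$scale[j])
      hi <- min(b, ps$loc[j] + ps$scale[j])
      if (hi <= lo) stop("inadmissible psi: sub-box does not intersect the base box")
      ld <- ifelse(x >= lo & x <= hi, -log(hi - lo), -Inf)
    }
    out <- out + ld
  }
  unname(out)
}
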
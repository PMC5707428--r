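# Local ordinary-kriging surrogate of the sampler objective, with the
# acceptance rules that guard against extrapolation.

#' Surrogate settings
#'
#' Controls the local kriging surrogate that can stand in for true
#' objective (log-likelihood) evaluations inside [run_tmcmc()]. For each
#' chain leader a box of width one quarter of the sampling domain per
#' dimension is centred on the leader (clipped to the domain) and an
#' ordinary-kriging interpolant is trained on the truly-evaluated points
#' inside. A prediction replaces a true evaluation only when (i) the box
#' holds at least `2 d + 1` training points, (ii) the kriging standard
#' error is at most `err_frac` of the predicted value's magnitude, and
#' (iii) the prediction lies inside the `band` quantile range of all true
#' objective values observed so far. Every rejected prediction falls back
#' to exactly one true evaluation.
#'
#' @param enabled Use the surrogate? Default `TRUE`.
#' @param err_frac Relative-error acceptance bound (default 0.05, the 5%
#'   rule). Values near zero therefore auto-reject, which is safe.
#' @param band Quantile band of observed objective values that predictions
#'   must fall inside (default `c(0.05, 0.95)`).
#' @param box_frac Box width as a fraction of the domain width per
#'   dimension (default 0.25, the quarter-domain rule).
#' @param min_points Minimum training points; default `2 * d + 1`.
#' @param nugget Relative nugget added to the kernel diagonal (default 1e-8).
#' @param max_points Cap on training points per box, nearest to the leader
#'   (default 25), bounding the cost of each fit.
#' @return A list of class `"surrogate_control"`.
#' @export
surrogate_control <- function(enabled = TRUE, err_frac = 0.05,
                              band = c(0.05, 0.95), box_frac = 0.25,
                              min_points = NULL, nugget = 1e-8,
                              max_points = 25) {
  stopifnot(err_frac > 0, length(band) == 2L, band[1] < band[2],
            band[1] > 0, band[2] < 1, box_frac > 0, box_frac <= 1,
            nugget > 0, max_points >= 3)
  structure(list(enabled = enabled, err_frac = err_frac, band = band,
                 box_frac = box_frac, min_points = min_points,
                 nugget = nugget, max_points = as.integer(max_points)),
            class = "surrogate_control")
}

#' Build a leader's kriging box
#'
#' The training region for one chain leader: a box of width `box_frac`
#' (default one quarter) of the sampling domain per dimension, centred at
#' the leader and clipped to the domain, holding every truly-evaluated
#' point that falls inside.
#'
#' @param leader Numeric position of the chain leader (inside the domain).
#' @param domain An `"lj_prior"` or [sampling_box()].
#' @param X Matrix of truly-evaluated positions (may be `NULL`).
#' @param y Objective values at `X`.
#' @param box_frac Box width fraction (default 0.25).
#' @return List of class `"lj_kriging_box"` with `leader`, `lower`,
#'   `upper`, `X`, `y`.
#' @export
build_box <- function(leader, domain, X = NULL, y = NULL, box_frac = 0.25) {
  sup <- as_support(domain)
  leader <- as.numeric(leader)
  stopifnot(length(leader) == length(sup$names))
  half <- box_frac * (sup$upper - sup$lower) / 2
  lower <- pmax(sup$lower, leader - half)
  upper <- pmin(sup$upper, leader + half)
  if (!is.null(X) && nrow(X) > 0) {
    keep <- rep(TRUE, nrow(X))
    for (j in seq_along(lower))
      keep <- keep & X[, j] >= lower[j] & X[, j] <= upper[j]
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    fin <- is.finite(y)
    X <- X[fin, , drop = FALSE]; y <- y[fin]
  } else {
    X <- matrix(numeric(0), 0, length(lower)); y <- numeric(0)
  }
  structure(list(leader = leader, lower = lower, upper = upper,
                 X = X, y = y),
            class = "lj_kriging_box")
}

# Ordinary kriging with a squared-exponential kernel on box-scaled
# coordinates; the single lengthscale is fit by maximizing the
# concentrated marginal likelihood. Returns NULL when the fit is not
# usable (too few points, singular correlation).
kriging_fit <- function(box, nugget = 1e-8, max_points = 25) {
  m <- nrow(box$X)
  if (m < 3) return(NULL)
  scale <- pmax(box$upper - box$lower, 1e-300)
  Xs <- sweep(box$X, 2, box$lower, "-")
  Xs <- sweep(Xs, 2, scale, "/")
  if (m > max_points) {
    ls <- (box$leader - box$lower) / scale
    d2l <- rowSums(sweep(Xs, 2, ls, "-")^2)
    keep <- order(d2l)[seq_len(max_points)]
    Xs <- Xs[keep, , drop = FALSE]
    y <- box$y[keep]
    m <- max_points
  } else y <- box$y
  D2 <- as.matrix(stats::dist(Xs))^2
  ones <- rep(1, m)
  nll <- function(log_ell) {
    ell <- exp(log_ell)
    R <- exp(-D2 / (2 * ell^2)) + diag(nugget, m)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Ri_y <- backsolve(ch, forwardsolve(t(ch), y))
    Ri_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    mu <- sum(Ri_y) / sum(Ri_1)
    res <- y - mu
    Ri_r <- Ri_y - mu * Ri_1
    s2 <- max(sum(res * Ri_r) / m, 1e-300)
    m / 2 * log(s2) + sum(log(diag(ch)))
  }
  opt <- stats::optimize(nll, c(log(0.05), log(3)), tol = 0.05)
  ell <- exp(opt$minimum)
  R <- exp(-D2 / (2 * ell^2)) + diag(nugget, m)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Ri <- chol2inv(ch)
  Ri_1 <- Ri %*% ones
  mu <- sum(Ri %*% y) / sum(Ri_1)
  res <- y - mu
  s2 <- max(sum(res * (Ri %*% res)) / m, 0)
  list(Xs = Xs, y = y, lower = box$lower, scale = scale, ell = ell,
       Ri = Ri, Ri_res = Ri %*% res, Ri_1 = Ri_1, one_Ri_1 = sum(Ri_1),
       mu = mu, s2 = s2, nugget = nugget, m = m)
}

kriging_mean_se <- function(fit, point) {
  xs <- (as.numeric(point) - fit$lower) / fit$scale
  d2 <- colSums((t(fit$Xs) - xs)^2)
  r <- exp(-d2 / (2 * fit$ell^2))
  mean_ <- fit$mu + sum(r * fit$Ri_res)
  rRir <- sum(r * (fit$Ri %*% r))
  oRr <- sum(r * fit$Ri_1)
  var_ <- fit$s2 * (1 + fit$nugget - rRir + (1 - oRr)^2 / fit$one_Ri_1)
  list(mean = mean_, se = sqrt(max(var_, 0)))
}

#' Kriging prediction with acceptance decision
#'
#' Predicts the objective at a point inside a leader's [build_box()] and
#' applies the surrogate acceptance rules: enough training points
#' (`>= 2 d + 1` by default), kriging standard error at most `err_frac`
#' of the predicted magnitude, and prediction inside the quantile band of
#' all truly-observed objective values. A singular or under-determined
#' fit yields a `too_few_points` decision (the sampler then falls back to
#' a true evaluation); it is never an error.
#'
#' @param box An `"lj_kriging_box"`.
#' @param point Prediction location inside the box bounds.
#' @param observed_values All true objective values observed so far
#'   (defines the quantile band).
#' @param control A [surrogate_control()].
#' @return List of class `"surrogate_decision"`: `value`,
#'   `predicted_error`, `accepted`, `reason` (one of `ok`,
#'   `error_gt_5pct`, `outside_quantile_band`, `too_few_points`).
#' @export
surrogate_predict <- function(box, point, observed_values,
                              control = surrogate_control()) {
  stopifnot(inherits(box, "lj_kriging_box"))
  point <- as.numeric(point)
  if (any(point < box$lower - 1e-12) || any(point > box$upper + 1e-12))
    stop("prediction point lies outside the kriging box")
  d <- length(box$lower)
  min_pts <- if (is.null(control$min_points)) 2L * d + 1L else control$min_points
  decision <- function(value, err, accepted, reason)
    structure(list(value = value, predicted_error = err,
                   accepted = accepted, reason = reason),
              class = "surrogate_decision")
  if (nrow(box$X) < min_pts)
    return(decision(NA_real_, NA_real_, FALSE, "too_few_points"))
  fit <- kriging_fit(box, control$nugget, control$max_points)
  if (is.null(fit))
    return(decision(NA_real_, NA_real_, FALSE, "too_few_points"))
  pr <- kriging_mean_se(fit, point)
  if (!is.finite(pr$mean) || !is.finite(pr$se))
    return(decision(NA_real_, NA_real_, FALSE, "too_few_points"))
  if (pr$se > control$err_frac * abs(pr$mean))
    return(decision(pr$mean, pr$se, FALSE, "error_gt_5pct"))
  qb <- stats::quantile(observed_values[is.finite(observed_values)],
                        control$band, type = 7)
  if (pr$mean < qb[1] || pr$mean > qb[2])
    return(decision(pr$mean, pr$se, FALSE, "outside_quantile_band"))
  decision(pr$mean, pr$se, TRUE, "ok")
}

#' @export
predict.lj_kriging_box <- function(object, point, observed_values,
                                   control = surrogate_control(), ...) {
  surrogate_predict(object, point, observed_values, control)
}

#' @export
print.surrogate_decision <- function(x, ...) {
  cat(sprintf("<surrogate_decision> value %.6g, se %.3g, %s (%s)\n",
              x$value, x$predicted_error,
              if (x$accepted) "accepted" else "rejected", x$reason))
  invisible(x)
}

# Stage-level surrogate evaluation used inside run_tmcmc: groups proposals
# by leader, builds one box + fit per unique leader, and falls back to a
# true evaluation whenever a prediction is rejected or the proposal left
# its leader's box. Truly-evaluated points are appended to the archive.
surrogate_stage_eval <- function(prop, idx, need, X_cur, arch_X, arch_y,
                                 sup, control, eval_true) {
  values <- numeric(length(need))
  stats <- list(calls = 0L, accepted = 0L, rejected = 0L, outside_box = 0L,
                true_evals = 0L,
                reasons = c(error_gt_5pct = 0L, outside_quantile_band = 0L,
                            too_few_points = 0L))
  leaders <- idx[need]
  for (lead in unique(leaders)) {
    rows <- which(leaders == lead)
    box <- build_box(X_cur[lead, ], sup, arch_X, arch_y, control$box_frac)
    for (r in rows) {
      pt <- prop[need[r], ]
      inbox <- all(pt >= box$lower) && all(pt <= box$upper)
      dec <- NULL
      if (inbox) {
        stats$calls <- stats$calls + 1L
        dec <- surrogate_predict(box, pt, arch_y, control)
      } else stats$outside_box <- stats$outside_box + 1L
      if (!is.null(dec) && dec$accepted) {
        stats$accepted <- stats$accepted + 1L
        values[r] <- dec$value
      } else {
        if (!is.null(dec)) {
          stats$rejected <- stats$rejected + 1L
          stats$reasons[dec$reason] <- stats$reasons[dec$reason] + 1L
        }
        yv <- eval_true(pt)
        stats$true_evals <- stats$true_evals + 1L
        values[r] <- yv
        if (is.finite(yv)) {
          arch_X <- rbind(arch_X, pt)
          arch_y <- c(arch_y, yv)
        }
      }
    }
  }
  list(values = values, arch_X = arch_X, arch_y = arch_y, stats = stats)
}
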
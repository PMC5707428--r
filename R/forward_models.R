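# Forward models mapping LJ parameters to observable curves, plus the
# adapter contract for an external molecular-dynamics engine.

#' Thermodynamic condition
#'
#' Label and (optional) state point of one observable dataset, e.g. the
#' liquid conditions `L1`..`L5`, the saturated-vapor condition `V`, or the
#' gas-phase quantum dimer scan `Q` (which carries no (T, P)).
#'
#' @param label Short text label.
#' @param temperature Temperature in K, `> 0`, or `NULL` for dimer data.
#' @param pressure Pressure in atm, or `NULL`.
#' @return An object of class `"lj_condition"`.
#' @export
lj_condition <- function(label, temperature = NULL, pressure = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.null(temperature)) {
    stopifnot(is.numeric(temperature), length(temperature) == 1L)
    if (!is.finite(temperature) || temperature <= 0)
      stop("'temperature' must be positive (K)")
  }
  structure(list(label = label, temperature = temperature, pressure = pressure),
            class = "lj_condition")
}

#' Observable curve dataset
#'
#' One observable curve on an ordered grid of separations: either a radial
#' distribution function g(r) (dimensionless) or a dimer binding-energy
#' scan E(r) (kcal/mol). This is the data container consumed by the
#' likelihood and by [lj_calibrate()].
#'
#' @param kind `"rdf"` or `"dimer_energy"`.
#' @param r Strictly increasing, positive separations (Angstrom), length >= 2.
#' @param values Observed curve, same length as `r`.
#' @param condition An [lj_condition()]; RDF data must carry a temperature.
#' @return An object of class `"lj_dataset"`.
#' @export
lj_dataset <- function(kind = c("rdf", "dimer_energy"), r, values,
                       condition = lj_condition("unnamed")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(r), is.numeric(values))
  if (length(r) < 2L) stop("'r' must have length >= 2")
  if (length(r) != length(values)) stop("'r' and 'values' lengths differ")
  if (any(!is.finite(r)) || any(r <= 0)) stop("'r' must be positive and finite")
  if (any(diff(r) <= 0)) stop("'r' must be strictly increasing")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (!inherits(condition, "lj_condition")) stop("'condition' must be an lj_condition")
  if (kind == "rdf" && is.null(condition$temperature))
    stop("RDF datasets need a temperature in their condition")
  structure(list(kind = kind, r = as.numeric(r), values = as.numeric(values),
                 condition = condition),
            class = "lj_dataset")
}

#' @export
print.lj_dataset <- function(x, ...) {
  tp <- if (!is.null(x$condition$temperature))
    sprintf(" at T = %.4g K", x$condition$temperature) else ""
  cat(sprintf("<lj_dataset> %s '%s'%s, %d points, r in [%.3g, %.3g] A\n",
              x$kind, x$condition$label, tp, length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

#' Dimer binding-energy forward model
#'
#' The model curve for a gas-phase dimer energy scan is the pair potential
#' itself, evaluated without truncation: a quantum dimer scan probes the
#' attractive tail well beyond \eqn{3\sigma}, where a hard zero would be
#' unphysical for curve fitting.
#'
#' @param params [lj_params()].
#' @param r_grid Separations in Angstrom.
#' @return Energies in kcal/mol over `r_grid`.
#' @export
dimer_energy_model <- function(params, r_grid) {
  lj_energy(r_grid, params, truncated = FALSE)
}

#' Dilute-gas radial distribution function model
#'
#' Closed-form low-density stand-in for an MD-computed RDF:
#' \eqn{g(r) = \exp(-V_{trunc}(r) / k_B T)} with the hard-truncated
#' potential, so g(r) = 1 exactly beyond the \eqn{3\sigma} cutoff and at
#' the zero crossing \eqn{r = \sigma}. It preserves the parameter
#' sensitivities that drive the calibration (sigma sets the peak location,
#' epsilon its height) while evaluating in microseconds. The exponent is
#' clipped at `±clip` to keep deep-well proposals finite and ordered.
#'
#' @param params [lj_params()].
#' @param condition [lj_condition()] carrying the temperature.
#' @param r_grid Separations in Angstrom.
#' @param clip Bound on the exponent argument (default 50).
#' @return Dimensionless g(r) over `r_grid`, everywhere `> 0`.
#' @export
dilute_rdf_model <- function(params, condition, r_grid, clip = 50) {
  if (is.null(condition$temperature) || condition$temperature <= 0)
    stop("RDF model needs a positive temperature in the condition")
  v <- lj_energy(r_grid, params, truncated = TRUE)
  a <- -v / (kB * condition$temperature)
  exp(pmin(pmax(a, -clip), clip))
}

#' Forward-model contract
#'
#' Wraps an evaluation function into the common forward-model interface
#' used by the sampler and the prediction machinery: deterministic in
#' `(params, condition, r_grid)` and returning one model value per grid
#' point.
#'
#' @param evaluate Function `(params, condition, r_grid) -> numeric`.
#' @param descriptor One-line description of the model.
#' @return An object of class `"lj_forward_model"` (callable list).
#' @export
forward_model <- function(evaluate, descriptor = "user forward model") {
  stopifnot(is.function(evaluate))
  structure(list(evaluate = evaluate, descriptor = descriptor),
            class = "lj_forward_model")
}

#' Built-in forward model for a dataset kind
#'
#' @param kind `"rdf"` or `"dimer_energy"`.
#' @return An `"lj_forward_model"` dispatching to [dilute_rdf_model()] or
#'   [dimer_energy_model()].
#' @export
builtin_forward_model <- function(kind = c("rdf", "dimer_energy")) {
  kind <- match.arg(kind)
  fm <- if (kind == "dimer_energy")
    forward_model(function(params, condition, r_grid)
      dimer_energy_model(params, r_grid),
      "untruncated LJ 6-p dimer binding energy")
  else
    forward_model(function(params, condition, r_grid)
      dilute_rdf_model(params, condition, r_grid),
      "dilute-gas RDF exp(-V_trunc / kB T)")
  fm$evaluate_batch <- function(theta, condition, r_grid)
    batch_curves(theta, condition, r_grid, kind)
  fm
}

# Vectorized curve evaluation over a matrix of parameter rows (columns
# epsilon, sigma, optionally p). Identical arithmetic to the scalar
# models, organized as n x length(r_grid) matrix operations.
batch_curves <- function(theta, condition, r_grid, kind, clip = 50) {
  eps <- theta[, "epsilon"]
  sig <- theta[, "sigma"]
  p <- if ("p" %in% colnames(theta)) theta[, "p"] else rep(12, nrow(theta))
  lsr <- outer(log(sig), log(r_grid), "-")     # log(sigma_i / r_j)
  E <- 4 * eps * (exp(p * lsr) - exp(6 * lsr)) # eps, p recycle over rows
  if (kind == "dimer_energy") return(E)
  E[outer(3 * sig, r_grid, ">=") == FALSE] <- 0  # hard cutoff at 3 sigma
  a <- -E / (kB * condition$temperature)
  exp(pmin(pmax(a, -clip), clip))
}

#' Evaluate a forward model with contract checks
#'
#' @param model An `"lj_forward_model"`.
#' @param params [lj_params()].
#' @param condition [lj_condition()].
#' @param r_grid Separations.
#' @return Model curve, guaranteed the same length as `r_grid`.
#' @export
eval_forward_model <- function(model, params, condition, r_grid) {
  stopifnot(inherits(model, "lj_forward_model"))
  out <- model$evaluate(params, condition, r_grid)
  if (!is.numeric(out) || length(out) != length(r_grid))
    stop(sprintf("forward model '%s' returned %d values for a %d-point grid",
                 model$descriptor, length(out), length(r_grid)))
  as.numeric(out)
}

#' Register an external simulation engine as a forward model
#'
#' Adapter contract for a real molecular-dynamics engine. The descriptor
#' names a command template with placeholders `{epsilon}`, `{sigma}`,
#' `{p}`, `{T}`, `{P}` substituted per evaluation; the engine must write a
#' two-column whitespace-delimited r/value table to stdout (or to the file
#' named by `{out}`). The reference MD protocol this adapter is meant to
#' front is recorded in `protocol`: 666 atoms under periodic boundaries,
#' NPT equilibration of 5e6 steps of 2 fs, NVE production of 1e5 steps,
#' RDF accumulated over 100 bins. The package never implements the engine
#' itself; failures to run or to parse are reported as errors carrying the
#' captured output.
#'
#' @param command Command template (character scalar) with placeholders.
#' @param parse Function mapping the engine's raw output lines to a
#'   two-column numeric matrix (r, value). Default parses whitespace-
#'   delimited numbers, ignoring `#` comments.
#' @return An `"lj_forward_model"` that shells out per evaluation.
#' @export
register_external_engine <- function(command, parse = parse_engine_table) {
  stopifnot(is.character(command), length(command) == 1L, is.function(parse))
  exe <- strsplit(trimws(command), "[[:space:]]+")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe))
    stop(sprintf("engine executable '%s' not found", exe))
  protocol <- list(atoms = 666, boundaries = "periodic",
                   npt_steps = 5e6, nve_steps = 1e5,
                   timestep_fs = 2, rdf_bins = 100)
  evaluate <- function(params, condition, r_grid) {
    cmd <- command
    sub1 <- function(key, val) gsub(key, format(val, digits = 15), cmd, fixed = TRUE)
    cmd <- sub1("{epsilon}", params$epsilon)
    cmd <- sub1("{sigma}", params$sigma)
    cmd <- sub1("{p}", params$p)
    if (!is.null(condition$temperature)) cmd <- sub1("{T}", condition$temperature)
    if (!is.null(condition$pressure)) cmd <- sub1("{P}", condition$pressure)
    out <- tryCatch(system(cmd, intern = TRUE),
                    warning = function(w) stop(sprintf(
                      "engine command failed: %s", conditionMessage(w))))
    tab <- parse(out)
    if (nrow(tab) != length(r_grid))
      stop(sprintf("engine returned %d rows for a %d-point grid (command: %s)",
                   nrow(tab), length(r_grid), command))
    as.numeric(tab[, 2])
  }
  fm <- forward_model(evaluate, sprintf("external engine: %s", command))
  fm$protocol <- protocol
  fm
}

#' Parse a two-column engine output table
#'
#' @param lines Character vector of raw output lines; `#` comments and
#'   blank lines are ignored.
#' @return Two-column numeric matrix.
#' @export
parse_engine_table <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("engine output contains no data rows")
  fields <- strsplit(lines, "[[:space:],]+")
  n <- vapply(fields, length, 1L)
  if (any(n < 2L))
    stop(sprintf("engine output row %d has fewer than 2 columns",
                 which(n < 2L)[1]))
  vals <- suppressWarnings(
    t(vapply(fields, function(f) as.numeric(f[1:2]), numeric(2))))
  bad <- which(!stats::complete.cases(vals))
  if (length(bad))
    stop(sprintf("engine output row %d is not numeric", bad[1]))
  vals
}
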
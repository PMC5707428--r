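# Curve-table and ensemble I/O, run manifests, and the in-process command
# dispatcher.

#' Read a two-column curve table
#'
#' Parses a whitespace- or comma-delimited r/value table (`#` comments
#' and blank lines ignored) into an [lj_dataset()]. Metadata comes from a
#' JSON sidecar `<path>.json` (written by [write_curve_table()]) when
#' present, else from the arguments.
#'
#' @param path File path.
#' @param kind,condition Metadata used when no sidecar exists; the default
#'   kind is `"dimer_energy"` since a bare table carries no temperature.
#' @return An [lj_dataset()]; when the sidecar records a generating
#'   truth it is restored as the `truth` attribute.
#' @export
read_curve_table <- function(path, kind = "dimer_energy",
                             condition = lj_condition("unnamed")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  raw <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(raw)))
  if (length(keep) < 2L) stop(sprintf("%s: fewer than 2 data rows", path))
  fields <- strsplit(trimws(raw[keep]), "[[:space:],]+")
  for (i in seq_along(fields)) {
    f <- suppressWarnings(as.numeric(fields[[i]][1:2]))
    if (length(fields[[i]]) < 2L || any(!is.finite(f)))
      stop(sprintf("%s line %d: expected two numeric columns", path, keep[i]))
    fields[[i]] <- f
  }
  tab <- do.call(rbind, fields)
  bad <- which(diff(tab[, 1]) <= 0)
  if (length(bad))
    stop(sprintf("%s line %d: r values must be strictly increasing",
                 path, keep[bad[1] + 1L]))
  side <- paste0(path, ".json")
  truth <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$kind)) kind <- meta$kind
    if (!is.null(meta$condition))
      condition <- lj_condition(meta$condition$label,
                                meta$condition$temperature,
                                meta$condition$pressure)
    truth <- meta$truth
  }
  out <- lj_dataset(kind, tab[, 1], tab[, 2], condition)
  if (!is.null(truth)) attr(out, "truth") <- unlist(truth)
  out
}

#' Write a curve table with its JSON sidecar
#'
#' Full-precision two-column text table plus a `<path>.json` sidecar
#' recording kind, condition and (for synthetic data) the generating
#' truth and seed, so fixtures are self-describing.
#'
#' @param dataset An [lj_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "lj_dataset"))
  header <- sprintf("# %s curve '%s' (%d points)", dataset$kind,
                    dataset$condition$label, length(dataset$r))
  rows <- sprintf("%.17g %.17g", dataset$r, dataset$values)
  writeLines(c(header, rows), path)
  meta <- list(kind = dataset$kind,
               condition = dataset$condition[c("label", "temperature", "pressure")],
               truth = as.list(attr(dataset, "truth")),
               seed = attr(dataset, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Persist a posterior ensemble
#'
#' Samples as a CSV table (one row per sample, parameter columns plus
#' `log_prior` and `log_likelihood`) and a JSON sidecar with the
#' log-evidence, tempering schedule, seed and sampler settings.
#'
#' @param ensemble An `"lj_ensemble"` or `"lj_fit"`.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_ensemble <- function(ensemble, prefix) {
  ens <- as_ensemble(ensemble)
  tab <- cbind(as.data.frame(ens$samples),
               log_prior = ens$log_priors, log_likelihood = ens$log_liks)
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  meta <- list(log_evidence = ens$log_evidence,
               stage_exponents = ens$stage_exponents,
               seed = ens$seed, config = unclass(ens$config))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Load a persisted posterior ensemble
#'
#' @param prefix Path prefix used by [write_ensemble()].
#' @return An `"lj_ensemble"`.
#' @export
read_ensemble <- function(prefix) {
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  if (!file.exists(csv) || !file.exists(js))
    stop(sprintf("missing ensemble files %s(.csv/.json)", prefix))
  tab <- utils::read.csv(csv)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  par_cols <- setdiff(names(tab), c("log_prior", "log_likelihood"))
  structure(list(samples = as.matrix(tab[par_cols]),
                 log_liks = tab$log_likelihood, log_priors = tab$log_prior,
                 log_evidence = meta$log_evidence,
                 stage_exponents = meta$stage_exponents,
                 seed = meta$seed, config = meta$config),
            class = "lj_ensemble")
}

cli_usage <- function() {
  paste(
    "usage: lj_cli(c(subcommand, args...))",
    "subcommands:",
    "  synth     --preset <name> --out <file>",
    "  calibrate --data <file> --model <lj6-12|lj6-p> --out <prefix>",
    "            [--samples <n>] [--seed <int>] [--surrogate]",
    "  hb        --data <f1,f2,...> --model <m> --out <dir> [--family <fam>]",
    "            [--samples <n>] [--seed <int>]",
    "  select    --fit1 <prefix> --fit2 <prefix> --out <file>",
    "  predict   --fit <prefix> --data <file> --out <file> [--subsample <n>]",
    "            [--seed <int>]",
    sep = "\n")
}

cli_args <- function(argv) {
  out <- list(flags = character(0))
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
        out[[key]] <- argv[i + 1L]; i <- i + 2L
      } else { out$flags <- c(out$flags, key); i <- i + 1L }
    } else stop(sprintf("unexpected argument '%s'", a))
  }
  out
}

#' In-process command dispatcher
#'
#' Ties the pipeline stages into reproducible shell-style runs without
#' leaving R: `synth` writes a preset fixture, `calibrate` runs a
#' single-dataset TMCMC calibration, `hb` the hierarchical version,
#' `select` compares two persisted calibrations by Bayes factor, and
#' `predict` propagates a persisted posterior onto a dataset's grid and
#' reports the relative squared error against the observed curve. Every
#' run writes a JSON manifest recording the configuration, seed and
#' resulting evidences. Errors print a message and return a nonzero
#' status rather than throwing, mirroring a command-line tool.
#'
#' @param argv Character vector: subcommand followed by `--key value`
#'   arguments (see the usage message printed on error).
#' @return Integer exit status, invisibly: 0 on success.
#' @export
lj_cli <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0L) stop(cli_usage())
    cmd <- argv[1]
    a <- cli_args(argv[-1])
    need <- function(key) {
      v <- a[[key]]
      if (is.null(v)) stop(sprintf("missing --%s\n%s", key, cli_usage()))
      v
    }
    seed <- as.integer(if (is.null(a$seed)) 1L else a$seed)
    manifest <- list(command = cmd, args = a[setdiff(names(a), "flags")],
                     seed = seed, package_version = as.character(
                       utils::packageVersion("ljbayes")))
    if (cmd == "synth") {
      presets <- argon_presets()
      nm <- need("preset")
      if (!nm %in% names(presets))
        stop(sprintf("unknown preset '%s' (have: %s)", nm,
                     paste(names(presets), collapse = ", ")))
      write_curve_table(generate(presets[[nm]]), need("out"))
    } else if (cmd == "calibrate") {
      d <- read_curve_table(need("data"))
      model <- if (is.null(a$model)) "lj6-p" else a$model
      n <- as.integer(if (is.null(a$samples))
        if (model == "lj6-p") 4000 else 2000 else a$samples)
      surr <- if ("surrogate" %in% a$flags) surrogate_control() else NULL
      fit <- lj_calibrate(d, model,
                          control = tmcmc_control(n_samples = n, seed = seed),
                          surrogate = surr)
      write_ensemble(fit, need("out"))
      manifest$log_evidence <- log_evidence(fit)
      manifest$mpv <- as.list(mpv(fit))
      jsonlite::write_json(manifest, paste0(need("out"), "_manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    } else if (cmd == "hb") {
      paths <- strsplit(need("data"), ",")[[1]]
      ds <- lapply(paths, read_curve_table)
      model <- if (is.null(a$model)) "lj6-p" else a$model
      fam <- if (is.null(a$family)) "truncnorm" else a$family
      n <- as.integer(if (is.null(a$samples)) 1000 else a$samples)
      dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
      hb <- lj_hb(ds, model, fam,
                  control = hb_control(tmcmc_control(n_samples = n)),
                  seed = seed)
      for (nm in names(hb$refreshed)) {
        write_ensemble(hb$stage1[[nm]], file.path(a$out, paste0(nm, "_stage1")))
        write_ensemble(hb$refreshed[[nm]], file.path(a$out, paste0(nm, "_refreshed")))
      }
      manifest$stage1_log_evidences <-
        lapply(hb$stage1, log_evidence)
      manifest$hyper_log_evidence <- log_evidence(hb)
      manifest$ess <- as.list(hb$ess)
      jsonlite::write_json(manifest, file.path(a$out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    } else if (cmd == "select") {
      e1 <- read_ensemble(need("fit1"))
      e2 <- read_ensemble(need("fit2"))
      cmpr <- bayes_factor(e1$log_evidence, e2$log_evidence,
                           labels = c(a$fit1, a$fit2))
      manifest$log_evidences <- cmpr$log_evidences
      manifest$bayes_factor <- cmpr$bayes_factor
      jsonlite::write_json(manifest, need("out"), auto_unbox = TRUE,
                           digits = NA, null = "null")
    } else if (cmd == "predict") {
      ens <- read_ensemble(need("fit"))
      d <- read_curve_table(need("data"))
      ns <- as.integer(if (is.null(a$subsample)) 100 else a$subsample)
      pr <- robust_predict(ens, builtin_forward_model(d$kind), d$condition,
                           d$r, subsample = ns, seed = seed)
      manifest$prediction_error <- prediction_error(pr$mpv_curve, d$values)
      manifest$summary <- list(r = pr$r_grid, mpv = pr$mpv_curve,
                               q05 = pr$q05, q95 = pr$q95)
      jsonlite::write_json(manifest, need("out"), auto_unbox = TRUE,
                           digits = NA, null = "null")
    } else stop(sprintf("unknown subcommand '%s'\n%s", cmd, cli_usage()))
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
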
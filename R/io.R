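#' Read and write trace files
#'
#' Traces are stored as 2-column tab-delimited text with headers `time_s`
#' and `cm_fF` (capacitance) or `i_pA` (amperometry); units are checked via
#' the header names. `write_trace()` additionally writes a JSON sidecar
#' `<path>.json` with the ground-truth parameters when the trace carries a
#' `truth` attribute.
#'
#' @param path file path.
#' @param kind `"capacitance"` or `"amperometry"`.
#' @return `read_trace()` returns a [capacitance_trace()] or
#'   [amperometry_trace()]; `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path, kind = c("capacitance", "amperometry")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE)
  col <- if (kind == "capacitance") "cm_fF" else "i_pA"
  if (!all(c("time_s", col) %in% names(df)))
    stop("expected columns 'time_s' and '", col, "' in ", path)
  t <- df$time_s
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("time column must be finite and strictly increasing")
  if (kind == "capacitance") {
    capacitance_trace(t, df$cm_fF)
  } else {
    dts <- diff(t)
    if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
      stop("amperometry traces must be uniformly sampled")
    amperometry_trace(t, df$i_pA, fs = 1 / stats::median(dts))
  }
}

#' @rdname read_trace
#' @param trace the trace to write.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "capacitance_trace")) {
    df <- data.frame(time_s = trace$t, cm_fF = trace$cm)
  } else if (inherits(trace, "amperometry_trace")) {
    df <- data.frame(time_s = trace$t, i_pA = trace$i)
  } else stop("not a trace object")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth <- attr(trace, "truth")
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run an end-to-end analysis pipeline from a configuration
#'
#' Executes the requested stages in order and writes one JSON result file
#' per stage into `out_dir`, plus a `summary.json` embedding the seed, a
#' hash of the configuration and the package version, so that a rerun with
#' the same configuration and seed is byte-identical.
#'
#' Supported stages and their config blocks:
#' * `simulate_fit`: `kinetics` (named parameters of [flash_kinetics()] or,
#'   when `model = "delayed"`, [delayed_srp_kinetics()]), `sigma_cm`,
#'   `n_cells`; generates a cohort, runs [select_model()] and
#'   [classify_components()] per cell.
#' * `stereology`: fields of [stereology_input()] (per named condition).
#' * `fisher`: `a`, `b`, `c`, `d` counts.
#' * `titration`: `pre_ca` and `burst` vectors.
#'
#' @param config a named list or path to a YAML file.
#' @param out_dir output directory (created if missing).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stages))
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- tempfile(); on.exit(unlink(cfg_file))
  writeLines(yaml::as.yaml(config), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  meta <- list(seed = seed, config_md5 = cfg_hash,
               package_version = as.character(utils::packageVersion("poolkin")))
  results <- list()
  for (stage in config$stages) {
    message("[poolkin] stage: ", stage)
    res <- tryCatch(
      switch(stage,
        simulate_fit = .stage_simulate_fit(config, seed),
        stereology = .stage_stereology(config),
        fisher = .stage_fisher(config),
        titration = .stage_titration(config),
        stop("unknown stage: ", stage)),
      error = function(e) {
        message("[poolkin] stage FAILED: ", stage, ": ", conditionMessage(e))
        list(error = conditionMessage(e))
      })
    out <- c(meta, list(stage = stage, result = res))
    jsonlite::write_json(out, file.path(out_dir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    results[[stage]] <- res
    if (!is.null(res$error)) {
      summary <- c(meta, list(completed = names(results),
                              failed = stage))
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", stage, "' failed; partial outputs kept in ",
           out_dir)
    }
  }
  summary <- c(meta, list(completed = names(results)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(meta, list(results = results)))
}

.stage_simulate_fit <- function(config, seed) {
  sf <- config$simulate_fit %||% list()
  kp <- sf$kinetics %||% list(A1 = 50, tau1 = 0.015, A2 = 30, tau2 = 0.3,
                              A3 = 20)
  kin <- if (identical(sf$model, "delayed")) do.call(delayed_srp_kinetics, kp)
         else do.call(flash_kinetics, kp)
  n_cells <- sf$n_cells %||% 5
  sigma <- sf$sigma_cm %||% 2
  srp_upper <- sf$srp_upper %||% 1.0
  cells <- lapply(seq_len(n_cells), function(j) {
    tr <- generate_flash_trace(kin, noise = noise_spec(sigma_cm = sigma,
                                                       seed = seed + j))
    fit <- select_model(tr)
    asn <- classify_components(fit, srp_upper = srp_upper)
    list(model_id = fit$model_id, rss = fit$rss,
         params = unclass(fit$params),
         rrp_size_fF = asn$rrp_size, rrp_tau_s = asn$rrp_tau,
         srp_size_fF = asn$srp_size, srp_tau_s = asn$srp_tau,
         sustained_rate_fF_per_s = asn$sustained_rate)
  })
  list(truth = unclass(kin), n_cells = n_cells, sigma_cm_fF = sigma,
       cells = cells)
}

.stage_stereology <- function(config) {
  conds <- config$stereology
  stopifnot(is.list(conds), length(conds) > 0)
  lapply(conds, function(cc) {
    rounding <- cc$rounding %||% "full"
    cc$rounding <- NULL
    unclass(stereology_chain(do.call(stereology_input, cc),
                             rounding = rounding))
  })
}

.stage_fisher <- function(config) {
  f <- config$fisher
  list(table = c(a = f$a, b = f$b, c = f$c, d = f$d),
       p_two_sided = fisher_exact_2x2(f$a, f$b, f$c, f$d))
}

.stage_titration <- function(config) {
  tt <- config$titration
  bins <- bin_titration(unlist(tt$pre_ca), unlist(tt$burst))
  list(bins = as.data.frame(bins),
       n_excluded = attr(bins, "n_excluded"))
}
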
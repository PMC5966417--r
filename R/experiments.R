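## Replicate orchestration and parameter sweeps.

#' Run replicate simulations
#'
#' Runs `n` independent seeded simulations. A run whose language population
#' empties is a legal outcome ("total extinction"), recorded in the trace's
#' `extinction_generation`, not an error.
#'
#' @param params A [sim_params()] object (its `seed` is overridden per run).
#' @param n Number of replicates (>= 1).
#' @param seeds Integer vector of length `n`; defaults to
#'   `base_seed * 1000 + 1:n` derived from `params$seed`.
#' @param out_dir Optional directory: each run is written with
#'   [write_trace()] under `out_dir/run_<seed>` together with a
#'   `manifest.json` listing every run.
#' @param keep_final_state Passed to [run_simulation()] (default `FALSE` to
#'   keep replicate lists light).
#' @return A list of `coevo_trace` objects.
#' @export
run_replicates <- function(params, n, seeds = NULL, out_dir = NULL,
                           keep_final_state = FALSE) {
  stopifnot(n >= 1)
  if (is.null(seeds)) seeds <- params$seed * 1000L + seq_len(n)
  stopifnot(length(seeds) == n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- as.integer(seeds[i])
    traces[[i]] <- run_simulation(p, keep_final_state = keep_final_state)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    runs <- lapply(seq_len(n), function(i) {
      d <- file.path(out_dir, sprintf("run_%d", seeds[i]))
      write_trace(traces[[i]], d)
      list(seed = seeds[i], dir = basename(d),
           extinction_generation = traces[[i]]$extinction_generation)
    })
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("coevolang")),
           params = unclass(params), runs = runs),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  traces
}

#' First generation of the coevolutionary phase (proxy)
#'
#' Operational proxy for the start of the coevolutionary phase: the first
#' generation at which mean plasticity drops below half its running maximum.
#' An invented summary statistic for sweep tables, not a quantity the model
#' defines.
#'
#' @param trace A `coevo_trace`.
#' @return Generation index, or `NA` if the criterion is never met.
#' @export
coevolution_phase_start <- function(trace) {
  p <- trace$trace$mean_p
  if (!length(p)) return(NA_integer_)
  hit <- which(p < cummax(p) / 2)
  if (length(hit)) trace$trace$gen[hit[1]] else NA_integer_
}

#' One-axis parameter sweep
#'
#' Runs `replicates` simulations at each value of one [sim_params()] field
#' and summarises each cell. When the swept axis is `F` and `link_Fd` is
#' `TRUE` (default), the division threshold is set to `Fd = F * 300` in each
#' cell, so the sweep isolates the effect of the displacement unit on
#' cultural change.
#'
#' @param params Base parameter set.
#' @param axis Name of the swept `sim_params` field.
#' @param values Values to sweep over.
#' @param replicates Replicates per value (>= 1).
#' @param seeds Optional seed matrix source; defaults derive from
#'   `params$seed`, the cell index and the replicate index.
#' @param link_Fd Keep `Fd = F * 300` when sweeping `F`.
#' @return A list of class `param_sweep`: `summary` (one row per cell:
#'   `value`, `extinction_fraction`, `median_extinction_generation`,
#'   `mean_final_lang_pos`, `median_phase_start`) and `traces` (list of
#'   per-cell trace lists).
#' @export
parameter_sweep <- function(params, axis, values, replicates = 3,
                            seeds = NULL, link_Fd = TRUE) {
  stopifnot(axis %in% names(unclass(params)), length(values) >= 0,
            replicates >= 1)
  cells <- vector("list", length(values))
  rows <- vector("list", length(values))
  for (k in seq_along(values)) {
    p <- params
    p[[axis]] <- values[k]
    if (axis == "F" && link_Fd) p$Fd <- p$F * 300
    validate_sim_params(p)
    s <- if (is.null(seeds)) params$seed * 1000L + k * 100L + seq_len(replicates)
         else seeds[[k]]
    traces <- run_replicates(p, replicates, seeds = s)
    ext <- vapply(traces, function(tr) tr$extinction_generation, 1L)
    final_pos <- vapply(traces, function(tr) {
      t <- tr$trace
      if (nrow(t)) t$mean_lang_pos[nrow(t)] else NA_real_
    }, numeric(1))
    phase <- vapply(traces, coevolution_phase_start, 1L)
    rows[[k]] <- data.frame(
      value = values[k],
      extinction_fraction = mean(!is.na(ext)),
      median_extinction_generation = stats::median(ext, na.rm = TRUE),
      mean_final_lang_pos = mean(final_pos, na.rm = TRUE),
      median_phase_start = stats::median(phase, na.rm = TRUE))
    cells[[k]] <- traces
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(0), extinction_fraction = numeric(0),
               median_extinction_generation = numeric(0),
               mean_final_lang_pos = numeric(0),
               median_phase_start = numeric(0))
  structure(list(axis = axis, summary = summary, traces = cells),
            class = "param_sweep")
}

#' @export
print.param_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s\n", x$axis))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
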
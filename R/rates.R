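## Evolutionary rates in darwins, swept over measurement intervals.
##
## A darwin is one e-fold of change per unit time; here the time unit is one
## model generation (the model has no calendar mapping), not the
## palaeontological "per million years".

#' Evolutionary rate in darwins
#'
#' `d = (ln(v2) - ln(v1)) / dt`: the signed number of e-folds per generation
#' between two measurements of a positive trait value separated by `dt`.
#'
#' @param v1,v2 Positive trait values at the start and end of the interval.
#' @param dt Positive measurement interval, in generations.
#' @return The signed rate (vectorised over its arguments).
#' @examples
#' darwin_rate(1, exp(1), 1)   # one e-fold in one generation
#' darwin_rate(1, exp(2), 4)   # 0.5
#' @export
darwin_rate <- function(v1, v2, dt) {
  if (any(v1 <= 0) || any(v2 <= 0)) {
    stop("darwin_rate() requires positive trait values")
  }
  if (any(dt <= 0)) stop("darwin_rate() requires a positive interval")
  (log(v2) - log(v1)) / dt
}

rate_sample_schema <- function() {
  data.frame(dt = numeric(0), source = character(0),
             event_kind = character(0), v1 = numeric(0), v2 = numeric(0),
             rate_signed = numeric(0), rate = numeric(0))
}

## Shared by biological_rates / cultural_rates: evaluates (v1, v2) pairs at
## every dt, dropping pairs with a non-positive endpoint (ln undefined;
## positions can be clamped at 0 early in runs) and tallying the drops.
rate_samples <- function(v1, v2, dt_grid, source, event_kind = NA_character_) {
  ok <- v1 > 0 & v2 > 0
  n_skipped <- sum(!ok)
  v1 <- v1[ok]; v2 <- v2[ok]
  event_kind <- rep_len(event_kind, length(v1))
  out <- do.call(rbind, lapply(dt_grid, function(dt) {
    if (length(v1) == 0) return(rate_sample_schema())
    r <- darwin_rate(v1, v2, dt)
    data.frame(dt = dt, source = source, event_kind = event_kind,
               v1 = v1, v2 = v2, rate_signed = r, rate = abs(r))
  }))
  if (is.null(out)) out <- rate_sample_schema()
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Biological evolutionary rates over a grid of intervals
#'
#' The trait is the population mean innate ability, one value per
#' generation. For each interval `dt`, the series is cut into
#' non-overlapping windows (`t = 1, 1 + dt, 1 + 2 dt, ...`) and each
#' consecutive endpoint pair yields one rate sample `|darwin_rate|`.
#' Non-overlapping windows avoid double-counting autocorrelated samples.
#'
#' @param trace A `coevo_trace` (or its `trace` data frame).
#' @param dt_grid Numeric vector of measurement intervals (generations).
#' @return A data frame of rate samples (`dt`, `source = "biological"`,
#'   `v1`, `v2`, `rate_signed`, `rate`); windows with a non-positive mean
#'   trait are excluded and counted in the `n_skipped` attribute.
#' @export
biological_rates <- function(trace, dt_grid) {
  tr <- if (inherits(trace, "coevo_trace")) trace$trace else trace
  series <- tr$mean_a
  stopifnot(length(series) > max(dt_grid))
  pieces <- lapply(dt_grid, function(dt) {
    dt <- as.integer(dt)
    starts <- seq.int(1L, length(series) - dt, by = dt)
    rate_samples(series[starts], series[starts + dt], dt, "biological")
  })
  out <- do.call(rbind, pieces)
  attr(out, "n_skipped") <- sum(vapply(pieces, attr, 0, "n_skipped"))
  rownames(out) <- NULL
  out
}

#' Cultural evolutionary rates over a grid of intervals
#'
#' Per-event rates from the cultural event log: a change event yields one
#' (`v1` = position before, `v2` = after) pair; a division yields two (each
#' child against the parent); a fusion yields two (the fused language
#' against each parent); extinctions yield none. Each event pair is
#' re-evaluated at every `dt` on the grid — the event is treated as the
#' change observed over a measurement window of that length, which is what
#' produces the mechanical `1/dt` interval dependence the analysis studies.
#'
#' @param events Event table from a completed run (or a `coevo_trace`).
#' @param dt_grid Numeric vector of measurement intervals (generations).
#' @return A data frame of rate samples (`dt`, `source = "cultural"`,
#'   `event_kind`, `v1`, `v2`, `rate_signed`, `rate`), with skipped
#'   non-positive-endpoint pairs tallied in the `n_skipped` attribute.
#' @export
cultural_rates <- function(events, dt_grid) {
  ev <- if (inherits(events, "coevo_trace")) events$events else events
  ch <- ev[ev$kind == "change", ]
  dv <- ev[ev$kind == "division", ]
  fu <- ev[ev$kind == "fusion", ]
  v1 <- c(ch$parent1, dv$parent1, dv$parent1, fu$parent1, fu$parent2)
  v2 <- c(ch$child1, dv$child1, dv$child2, fu$child1, fu$child1)
  kind <- c(rep("change", nrow(ch)), rep("division", 2L * nrow(dv)),
            rep("fusion", 2L * nrow(fu)))
  out <- rate_samples(v1, v2, dt_grid, "cultural", kind)
  rownames(out) <- NULL
  out
}

#' Rate-versus-interval sweep
#'
#' Aggregates biological and cultural rate samples per interval: medians and
#' quartiles of `|rate|` split by source, plus the Spearman correlation
#' between `dt` and the median cultural rate (negative when cultural rates
#' slow as the measurement interval grows).
#'
#' @param trace A `coevo_trace` (or trace data frame).
#' @param events Event table (defaults to the trace's own events).
#' @param dt_grid Numeric vector of measurement intervals.
#' @return A list of class `rate_sweep`: `summary` (data frame: `dt`,
#'   `source`, `n`, `median`, `q25`, `q75`, `n_skipped`), `samples`, and
#'   `spearman_cultural` (correlation of `dt` with median cultural rate).
#' @export
rate_interval_sweep <- function(trace, events = NULL, dt_grid) {
  if (inherits(trace, "coevo_trace") && is.null(events)) events <- trace$events
  bio <- biological_rates(trace, dt_grid)
  cul <- cultural_rates(events, dt_grid)
  samples <- rbind(bio, cul)
  skipped <- c(biological = attr(bio, "n_skipped"),
               cultural = attr(cul, "n_skipped"))
  summ <- do.call(rbind, lapply(split(samples, samples[c("dt", "source")],
                                      drop = TRUE), function(g) {
    q <- stats::quantile(g$rate, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(dt = g$dt[1], source = g$source[1], n = nrow(g),
               median = q[2], q25 = q[1], q75 = q[3],
               n_skipped = unname(skipped[g$source[1]]))
  }))
  summ <- summ[order(summ$source, summ$dt), ]
  rownames(summ) <- NULL
  med_cult <- summ[summ$source == "cultural", ]
  rho <- if (nrow(med_cult) >= 2 && stats::sd(med_cult$median) > 0) {
    stats::cor(med_cult$dt, med_cult$median, method = "spearman")
  } else NA_real_
  structure(list(summary = summ, samples = samples,
                 spearman_cultural = rho),
            class = "rate_sweep")
}

#' @export
print.rate_sweep <- function(x, ...) {
  cat("Evolutionary-rate sweep (darwins, generation time unit)\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Spearman(dt, median cultural rate) = %.3f\n",
              x$spearman_cultural))
  invisible(x)
}
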
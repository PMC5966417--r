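## Generation loop and the run-trace container.

#' Advance the model by one generation
#'
#' Executes, in order: all-pairs communication, fitness evaluation,
#' roulette-wheel reproduction with mutation, cultural change + division
#' (one displacement pass; a language either divides or moves), extinction,
#' fusion. Appends one trace row and all cultural events. The agent count is
#' invariant; an empty language population is a legal (stagnant) state.
#'
#' The trace row records the communicating generation's agent statistics
#' (mean `a`, `p`, fitness, number of successful pairs) and the language
#' statistics after all cultural processes (mean position, count).
#'
#' @param state A list with elements `agents`, `langs`, `next_id`,
#'   `generation` (as produced by [init_state()] or a previous call).
#' @param params A [sim_params()] object.
#' @return The updated state, with `trace_row` (one-row data frame) and
#'   `events` (event table for this generation) attached.
#' @export
step_generation <- function(state, params) {
  gen <- state$generation + 1L
  agents <- state$agents
  langs <- state$langs

  log <- run_communication_round(agents, langs)
  fit <- compute_fitness(agents, log, params)
  offspring <- reproduce_agents(agents, fit, params)

  cc <- apply_cultural_change(langs, log, agents, params, gen, state$next_id)
  ex <- apply_extinction(cc$langs, log, gen)
  fu <- apply_fusion(ex$langs, params, gen, cc$next_id)

  events <- rbind(cc$events, ex$events, fu$events)
  langs2 <- fu$langs

  trace_row <- data.frame(
    gen = gen,
    mean_a = mean(agents$a),
    mean_p = mean(agents$p),
    mean_fitness = mean(fit),
    mean_lang_pos = if (nrow(langs2)) mean(langs2$pos) else NA_real_,
    n_langs = nrow(langs2),
    n_successes = length(log$pair_i))

  list(agents = offspring, langs = langs2, next_id = fu$next_id,
       generation = gen, trace_row = trace_row, events = events)
}

#' Draw the initial model state
#'
#' Initial genotypes `a_i`, `p_i` and language positions `l_x` are i.i.d.
#' uniform on `[0, 1]`. Consumes the current RNG state.
#'
#' @param params A [sim_params()] object.
#' @return A state list (`agents`, `langs`, `next_id`, `generation = 0`).
#' @export
init_state <- function(params) {
  agents <- new_agents(stats::runif(params$N), stats::runif(params$N))
  k <- params$init_num_languages
  langs <- new_languages(stats::runif(k), seq_len(k))
  list(agents = agents, langs = langs, next_id = k + 1L, generation = 0L)
}

#' Run a full simulation
#'
#' Seeds the RNG from `params$seed`, draws the initial state and iterates
#' [step_generation()] for `params$generations` generations. Identical
#' `params` (including the seed) give a bit-identical trace.
#'
#' @param params A [sim_params()] object.
#' @param keep_final_state Keep the final agent/language populations in the
#'   result (default `TRUE`).
#' @return An object of class `coevo_trace`: a list with
#'   \describe{
#'     \item{trace}{data frame, one row per generation: `gen`, `mean_a`,
#'       `mean_p`, `mean_fitness`, `mean_lang_pos`, `n_langs`,
#'       `n_successes`.}
#'     \item{events}{data frame of cultural events (`kind` in change /
#'       division / fusion / extinction, positions and lineage ids involved).}
#'     \item{params}{the resolved parameters.}
#'     \item{extinction_generation}{first generation with zero languages
#'       (`NA` if the language population never emptied).}
#'     \item{final_state}{final populations, if kept.}
#'   }
#' @examples
#' tr <- run_simulation(sim_params(N = 20, generations = 50,
#'                                 init_num_languages = 10, seed = 7))
#' tail(tr$trace, 3)
#' @export
run_simulation <- function(params, keep_final_state = TRUE) {
  validate_sim_params(params)
  set.seed(params$seed)
  state <- init_state(params)
  g <- params$generations
  rows <- vector("list", g)
  evts <- vector("list", g)
  for (t in seq_len(g)) {
    state <- step_generation(state, params)
    rows[[t]] <- state$trace_row
    evts[[t]] <- state$events
  }
  trace <- if (g > 0) do.call(rbind, rows) else
    step_trace_schema()
  events <- if (g > 0) do.call(rbind, evts) else empty_events()
  rownames(trace) <- rownames(events) <- NULL
  ext <- trace$gen[trace$n_langs == 0][1]
  structure(list(trace = trace, events = events, params = params,
                 extinction_generation = if (length(ext)) ext else NA_integer_,
                 final_state = if (keep_final_state)
                   state[c("agents", "langs", "next_id", "generation")]
                 else NULL),
            class = "coevo_trace")
}

step_trace_schema <- function() {
  data.frame(gen = integer(0), mean_a = numeric(0), mean_p = numeric(0),
             mean_fitness = numeric(0), mean_lang_pos = numeric(0),
             n_langs = integer(0), n_successes = integer(0))
}

#' @export
print.coevo_trace <- function(x, ...) {
  g <- nrow(x$trace)
  cat(sprintf("Coevolution run: N = %d, %d generations, seed = %d\n",
              x$params$N, g, x$params$seed))
  if (g > 0) {
    last <- x$trace[g, ]
    cat(sprintf("  final: mean a = %.4f, mean p = %.4f, %d languages, %d successful pairs\n",
                last$mean_a, last$mean_p, last$n_langs, last$n_successes))
  }
  tab <- table(x$events$kind)
  if (length(tab)) {
    cat("  events:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.na(x$extinction_generation)) {
    cat(sprintf("  total language extinction at generation %d\n",
                x$extinction_generation))
  }
  invisible(x)
}

#' Plot a run trace
#'
#' Two stacked panels in the style of standard evolution plots: mean
#' language position and mean innate ability with the language count on a
#' secondary axis, then mean plasticity and successful-communication count.
#' Inspection aid only.
#'
#' @param x A `coevo_trace`.
#' @param ... Unused.
#' @export
plot.coevo_trace <- function(x, ...) {
  tr <- x$trace
  if (nrow(tr) == 0) {
    warning("empty trace; nothing to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 4))
  on.exit(graphics::par(op))
  ylim <- range(c(tr$mean_a, tr$mean_lang_pos), na.rm = TRUE, finite = TRUE)
  plot(tr$gen, tr$mean_lang_pos, type = "l", col = "darkgreen",
       xlab = "generation", ylab = "mean position", ylim = ylim)
  graphics::lines(tr$gen, tr$mean_a, col = "red")
  graphics::par(new = TRUE)
  plot(tr$gen, tr$n_langs, type = "l", col = "blue", axes = FALSE,
       xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("languages", side = 4, line = 2.5)
  graphics::legend("topleft", legend = c("mean l_x", "mean a", "# languages"),
                   col = c("darkgreen", "red", "blue"), lty = 1, bty = "n",
                   cex = 0.8)
  plot(tr$gen, tr$mean_p, type = "l", col = "darkgreen",
       xlab = "generation", ylab = "mean plasticity")
  graphics::par(new = TRUE)
  plot(tr$gen, tr$n_successes, type = "l", col = "red", axes = FALSE,
       xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("successes", side = 4, line = 2.5)
  invisible(x)
}
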
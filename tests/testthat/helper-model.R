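# Shared helpers: hand-built communication logs and brute-force oracles.

# Build a comm_log by hand from explicit success records.
# successes: data.frame(i, j, lang) with lang an index into langs.
manual_log <- function(successes, langs, n_agents, usable_counts) {
  if (nrow(successes)) {
    ag <- c(successes$i, successes$j)
    lg <- c(successes$lang, successes$lang)
    keep <- !duplicated(paste(lg, ag))
    users <- data.frame(lang = lg[keep], agent = ag[keep])
  } else {
    users <- data.frame(lang = integer(0), agent = integer(0))
  }
  structure(list(pair_i = successes$i, pair_j = successes$j,
                 pair_lang = successes$lang,
                 pair_lang_pos = langs$pos[successes$lang],
                 usable_counts = usable_counts,
                 users = users,
                 lang_pos = langs$pos, lang_lineage = langs$lineage_id),
            class = "comm_log")
}

# O(n^2 * L) brute-force oracle for pairwise shared-language counts.
brute_shared <- function(agents, langs) {
  n <- nrow(agents)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sh <- shared_languages(agents[i, ], agents[j, ], langs)
      out[[length(out) + 1]] <- data.frame(i = i, j = j, n_shared = nrow(sh))
    }
  }
  do.call(rbind, out)
}

# Term-by-term brute-force plug-in transfer entropy T_{y->x}, m = l = 1,
# enumerating observed (x_{t+1}, x_t, y_t) triples and counting directly.
brute_te <- function(x, y, base = 2) {
  n <- length(x)
  trip <- data.frame(xn = x[2:n], xt = x[1:(n - 1)], yt = y[1:(n - 1)])
  uniq <- unique(trip)
  total <- nrow(trip)
  te <- 0
  for (r in seq_len(nrow(uniq))) {
    xn <- uniq$xn[r]; xt <- uniq$xt[r]; yt <- uniq$yt[r]
    n_xyz <- sum(trip$xn == xn & trip$xt == xt & trip$yt == yt)
    n_xy  <- sum(trip$xt == xt & trip$yt == yt)
    n_xnx <- sum(trip$xn == xn & trip$xt == xt)
    n_x   <- sum(trip$xt == xt)
    p_joint <- n_xyz / total
    te <- te + p_joint * log((n_xyz / n_xy) / (n_xnx / n_x), base = base)
  }
  te
}

# Small deterministic run used by several test files (cached per arguments).
.trace_cache <- new.env(parent = emptyenv())
tiny_trace <- function(seed = 42, N = 40, generations = 300,
                       init_num_languages = 10) {
  key <- paste(seed, N, generations, init_num_languages, sep = "_")
  if (is.null(.trace_cache[[key]])) {
    .trace_cache[[key]] <- run_simulation(
      sim_params(N = N, generations = generations,
                 init_num_languages = init_num_languages, seed = seed),
      keep_final_state = TRUE)
  }
  .trace_cache[[key]]
}
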
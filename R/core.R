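## Core agent/language state machine.
##
## One generation = communication -> fitness -> reproduction -> cultural
## change + division -> extinction -> fusion. All stochastic draws consume
## the current global RNG state, in that fixed order, so a run seeded once
## is bit-reproducible.

#' Construct an agent population
#'
#' Agents live on the same one-dimensional expressiveness axis as languages.
#' `a` is the innate language ability (the language usable at zero learning
#' cost), `p` the plasticity half-width: agent `i` can use any language in
#' `[a_i - p_i, a_i + p_i]`.
#'
#' @param a Numeric vector of innate abilities (>= 0).
#' @param p Numeric vector of plasticity half-widths (>= 0), recycled.
#' @return A data frame with columns `a`, `p`, `fitness` (initialised `NA`).
#' @export
new_agents <- function(a, p) {
  stopifnot(all(a >= 0), all(p >= 0))
  data.frame(a = as.numeric(a), p = rep_len(as.numeric(p), length(a)),
             fitness = NA_real_)
}

#' Construct a language population
#'
#' Each language is a point `pos >= 0` whose position encodes expressiveness
#' (the fitness benefit of one successful communication using it).
#' `lineage_id` is a stable identifier: it survives cultural change and is
#' re-keyed when a language divides or fuses.
#'
#' @param pos Numeric vector of language positions (>= 0).
#' @param lineage_id Integer identifiers, unique within the population.
#' @return A data frame with columns `pos`, `lineage_id`.
#' @export
new_languages <- function(pos, lineage_id = seq_along(pos)) {
  stopifnot(all(pos >= 0), !anyDuplicated(lineage_id))
  data.frame(pos = as.numeric(pos), lineage_id = as.integer(lineage_id))
}

#' Languages shared by two agents
#'
#' Returns the languages lying in the intersection of the two agents'
#' plasticity intervals, i.e. with
#' `max(a_i - p_i, a_j - p_j) <= pos <= min(a_i + p_i, a_j + p_j)`.
#' The pair can communicate successfully iff this set is non-empty.
#'
#' @param agent_i,agent_j Lists (or one-row data frames) with elements `a`, `p`.
#' @param langs Language population (see [new_languages()]); may be empty.
#' @return The subset of `langs` rows shared by both agents (possibly empty).
#' @examples
#' shared_languages(list(a = 0.5, p = 0.2), list(a = 0.8, p = 0.2),
#'                  new_languages(0.65))
#' @export
shared_languages <- function(agent_i, agent_j, langs) {
  lo <- max(agent_i$a - agent_i$p, agent_j$a - agent_j$p)
  hi <- min(agent_i$a + agent_i$p, agent_j$a + agent_j$p)
  langs[langs$pos >= lo & langs$pos <= hi, , drop = FALSE]
}

## All unordered pair indices of 1..n, as two integer vectors.
pair_indices <- function(n) {
  ni <- n - 1L
  list(i = rep.int(seq_len(ni), ni:1L),
       j = sequence(ni:1L) + rep.int(seq_len(ni), ni:1L))
}

#' Run one all-pairs communication round
#'
#' Every unordered pair of agents with at least one shared language
#' communicates successfully; exactly one shared language is drawn uniformly
#' at random for the pair and recorded symmetrically for both partners. The
#' log also records, per agent, the number of languages inside its own
#' plasticity interval (`n_i`, the repertoire size), computed on the
#' pre-change language positions.
#'
#' The all-pairs interval test is done with sorted language positions and
#' binary search (compiled; one uniform draw per successful pair, in pair
#' order), not by enumerating every (pair, language) combination. A plain-R
#' reference implementation of the same contract is kept for
#' cross-validation (`use_compiled = FALSE`); both produce bit-identical
#' logs from the same RNG state.
#'
#' @param agents Agent population (see [new_agents()]).
#' @param langs Language population; may be empty.
#' @param use_compiled Use the compiled pair loop (default) or the plain-R
#'   reference implementation.
#' @return An object of class `comm_log`: a list with elements
#'   `pair_i`, `pair_j` (agent indices of successful pairs),
#'   `pair_lang` (language index chosen for each pair),
#'   `pair_lang_pos` (its position), `usable_counts` (`n_i` per agent),
#'   `users` (data frame of unique (lang, agent) usage pairs),
#'   `benefit` (per-agent sum of chosen language positions),
#'   `lang_pos` and `lang_lineage` (language snapshot at communication time).
#' @export
run_communication_round <- function(agents, langs, use_compiled = TRUE) {
  n <- nrow(agents)
  stopifnot(n >= 2)
  if (nrow(langs) == 0) {
    return(structure(list(pair_i = integer(0), pair_j = integer(0),
                          pair_lang = integer(0), pair_lang_pos = numeric(0),
                          usable_counts = integer(n),
                          users = data.frame(lang = integer(0),
                                             agent = integer(0)),
                          benefit = numeric(n),
                          lang_pos = langs$pos,
                          lang_lineage = langs$lineage_id),
                     class = "comm_log"))
  }
  ord <- order(langs$pos)
  raw <- if (use_compiled) {
    comm_round_cpp(agents$a, agents$p, langs$pos[ord], as.integer(ord))
  } else {
    comm_round_r(agents$a, agents$p, langs$pos[ord], as.integer(ord))
  }
  structure(list(pair_i = raw$pair_i, pair_j = raw$pair_j,
                 pair_lang = raw$pair_lang,
                 pair_lang_pos = langs$pos[raw$pair_lang],
                 usable_counts = raw$usable_counts,
                 users = data.frame(lang = raw$users_lang,
                                    agent = raw$users_agent),
                 benefit = raw$benefit,
                 lang_pos = langs$pos, lang_lineage = langs$lineage_id),
            class = "comm_log")
}

## Plain-R reference for comm_round_cpp: same contract, same draw order.
comm_round_r <- function(a, p, ls, ord) {
  n <- length(a)
  lo <- a - p
  hi <- a + p
  usable <- findInterval(hi, ls) - findInterval(lo, ls, left.open = TRUE)
  out_empty <- list(pair_i = integer(0), pair_j = integer(0),
                    pair_lang = integer(0),
                    usable_counts = as.integer(usable),
                    users_lang = integer(0), users_agent = integer(0),
                    benefit = numeric(n))
  pr <- pair_indices(n)
  lo_ij <- pmax(lo[pr$i], lo[pr$j])
  hi_ij <- pmin(hi[pr$i], hi[pr$j])
  c_le <- findInterval(hi_ij, ls)
  c_lt <- findInterval(lo_ij, ls, left.open = TRUE)
  cnt <- c_le - c_lt
  ok <- cnt > 0L
  if (!any(ok)) return(out_empty)
  i_s <- pr$i[ok]; j_s <- pr$j[ok]
  cnt_s <- cnt[ok]; base_s <- c_lt[ok]
  pick <- base_s + pmin.int(floor(stats::runif(length(cnt_s)) * cnt_s),
                            cnt_s - 1) + 1L
  lang_idx <- ord[pick]
  pos <- ls[pick]
  benefit <- numeric(n)
  agg <- rowsum(c(pos, pos), c(i_s, j_s))
  benefit[as.integer(rownames(agg))] <- agg[, 1L]
  ag <- c(i_s, j_s)
  lg <- c(lang_idx, lang_idx)
  key <- (lg - 1L) * (n + 0.0) + ag
  o <- order(key)
  keep <- !duplicated(key[o])
  list(pair_i = i_s, pair_j = j_s, pair_lang = lang_idx,
       usable_counts = as.integer(usable),
       users_lang = lg[o][keep], users_agent = ag[o][keep],
       benefit = benefit)
}

#' Agent fitness
#'
#' `fitness_i = W1 * sum_{j in SC_i} l_{i,j} - W2 * (p_i + 1)^(a_i)`:
#' the summed expressiveness of the languages used in agent `i`'s successful
#' communications, minus a plasticity cost that grows exponentially with
#' innate ability. May be negative; selection weights are floored later.
#'
#' @param agents Agent population.
#' @param log A `comm_log` for the current generation.
#' @param params A [sim_params()] object (uses `W1`, `W2`).
#' @return Numeric vector of fitness values, one per agent.
#' @export
compute_fitness <- function(agents, log, params) {
  n <- nrow(agents)
  if (!is.null(log$benefit)) {
    benefit <- log$benefit
  } else {
    benefit <- numeric(n)
    if (length(log$pair_i)) {
      who <- c(log$pair_i, log$pair_j)
      w <- c(log$pair_lang_pos, log$pair_lang_pos)
      agg <- rowsum(w, who)
      benefit[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  params$W1 * benefit - params$W2 * (agents$p + 1)^agents$a
}

## Roulette-wheel selection weights: rank-preserving shift + positive floor.
selection_weights <- function(fitness, fitness_floor) {
  w <- fitness - min(fitness) + fitness_floor
  if (all(w <= 0)) stop("all selection weights are zero")
  w
}

#' Biological reproduction
#'
#' Produces the next agent generation: `N` parents drawn by roulette-wheel
#' selection proportional to floored fitness weights, each offspring copying
#' its parent's genotypes and each genotype (`a` and `p` independently)
#' mutated with probability `Pm` by a Gaussian increment with mean 0 and
#' variance `mut_var`, then clamped at 0.
#'
#' @param agents Agent population with valid genotypes.
#' @param fitnesses Numeric fitness vector (from [compute_fitness()]).
#' @param params A [sim_params()] object.
#' @return A new agent population of the same size.
#' @export
reproduce_agents <- function(agents, fitnesses, params) {
  n <- nrow(agents)
  w <- selection_weights(fitnesses, params$fitness_floor)
  parent <- sample.int(n, n, replace = TRUE, prob = w)
  a <- agents$a[parent]
  p <- agents$p[parent]
  if (params$Pm > 0 && params$mut_var > 0) {
    sd <- sqrt(params$mut_var)
    ma <- stats::runif(n) < params$Pm
    mp <- stats::runif(n) < params$Pm
    if (any(ma)) a[ma] <- a[ma] + stats::rnorm(sum(ma), 0, sd)
    if (any(mp)) p[mp] <- p[mp] + stats::rnorm(sum(mp), 0, sd)
  }
  new_agents(pmax(a, 0), pmax(p, 0))
}

#' Cultural displacement of each language
#'
#' Each agent that used language `x` at least once pulls it by `F / n_i`
#' toward the agent's innate ability: `d_plus` sums the pulls from users with
#' `a_i > l_x`, `d_minus` (stored non-positive) those from users with
#' `a_i < l_x`; users sitting exactly at `l_x` contribute to neither. The net
#' displacement is `d_plus + d_minus`.
#'
#' @param langs Language population (positions matching `log$lang_pos`).
#' @param log A `comm_log` for the current generation.
#' @param agents The agent population that communicated.
#' @param params A [sim_params()] object (uses `F`).
#' @return A data frame with one row per language: `d_plus` (>= 0) and
#'   `d_minus` (<= 0). Unused languages get (0, 0).
#' @export
language_displacement <- function(langs, log, agents, params) {
  nl <- nrow(langs)
  d_plus <- numeric(nl)
  d_minus <- numeric(nl)
  u <- log$users
  if (nrow(u)) {
    pull <- params$F / log$usable_counts[u$agent]
    rel <- agents$a[u$agent] - langs$pos[u$lang]
    up <- rel > 0
    dn <- rel < 0
    if (any(up)) {
      agg <- rowsum(pull[up], u$lang[up])
      d_plus[as.integer(rownames(agg))] <- agg[, 1L]
    }
    if (any(dn)) {
      agg <- rowsum(pull[dn], u$lang[dn])
      d_minus[as.integer(rownames(agg))] <- -agg[, 1L]
    }
  }
  data.frame(d_plus = d_plus, d_minus = d_minus)
}

## Empty cultural-event table (schema shared by all event emitters).
empty_events <- function() {
  data.frame(kind = character(0), generation = integer(0),
             parent1 = numeric(0), parent2 = numeric(0),
             child1 = numeric(0), child2 = numeric(0),
             parent1_id = integer(0), parent2_id = integer(0),
             child1_id = integer(0), child2_id = integer(0))
}

#' Build one cultural-event record
#'
#' Constructs a one-row event table in the schema used by run traces:
#' `kind` (change / division / fusion / extinction), `generation`, parent
#' and child positions, and the lineage ids involved. Mostly useful for
#' assembling synthetic event logs for [cultural_rates()].
#'
#' @param kind Event kind.
#' @param generation Generation number.
#' @param parent1,parent2 Parent positions (`NA` where absent).
#' @param child1,child2 Child positions (`NA` where absent).
#' @param parent1_id,parent2_id,child1_id,child2_id Lineage ids.
#' @return A one-row data frame.
#' @export
event_row <- function(kind, generation, parent1 = NA_real_, parent2 = NA_real_,
                      child1 = NA_real_, child2 = NA_real_,
                      parent1_id = NA_integer_, parent2_id = NA_integer_,
                      child1_id = NA_integer_, child2_id = NA_integer_) {
  data.frame(kind = kind, generation = as.integer(generation),
             parent1 = parent1, parent2 = parent2,
             child1 = child1, child2 = child2,
             parent1_id = parent1_id, parent2_id = parent2_id,
             child1_id = child1_id, child2_id = child2_id)
}

#' Cultural change and division
#'
#' Applies the displacement pass: a language pulled by more than `Fd` in both
#' directions at once (`min(d_plus, |d_minus|) > Fd`) is removed and replaced
#' by two children at `l_x + d_plus` and `l_x + d_minus` (division event);
#' otherwise it moves to `l_x + d_plus + d_minus`, emitting a change event
#' when the net displacement is nonzero. A language either divides or moves,
#' never both. Positions are clamped at 0.
#'
#' @param langs Language population.
#' @param log A `comm_log` for the current generation.
#' @param agents The agent population that communicated.
#' @param params A [sim_params()] object (uses `F`, `Fd`).
#' @param generation Generation number stamped on emitted events.
#' @param next_id Next free lineage identifier.
#' @return A list: `langs` (updated population, division children carry fresh
#'   lineage ids and a `division_child` attribute), `events` (event table),
#'   `next_id`.
#' @export
apply_cultural_change <- function(langs, log, agents, params,
                                  generation = 0L, next_id = NULL) {
  if (is.null(next_id)) next_id <- max(0L, langs$lineage_id) + 1L
  if (nrow(langs) == 0) {
    return(list(langs = langs, events = empty_events(), next_id = next_id))
  }
  d <- language_displacement(langs, log, agents, params)
  divide <- pmin(d$d_plus, -d$d_minus) > params$Fd
  moved <- !divide & (d$d_plus + d$d_minus) != 0

  keep <- langs[!divide, , drop = FALSE]
  old_pos <- keep$pos
  net <- (d$d_plus + d$d_minus)[!divide]
  keep$pos <- pmax(old_pos + net, 0)

  events <- empty_events()
  if (any(moved)) {
    m <- moved[!divide]
    events <- rbind(events, data.frame(
      kind = "change", generation = as.integer(generation),
      parent1 = old_pos[m], parent2 = NA_real_,
      child1 = keep$pos[m], child2 = NA_real_,
      parent1_id = keep$lineage_id[m], parent2_id = NA_integer_,
      child1_id = keep$lineage_id[m], child2_id = NA_integer_))
  }

  children <- NULL
  if (any(divide)) {
    pv <- langs$pos[divide]
    dp <- d$d_plus[divide]
    dm <- d$d_minus[divide]
    c1 <- pmax(pv + dp, 0)
    c2 <- pmax(pv + dm, 0)
    nd <- sum(divide)
    id1 <- next_id + 2L * seq_len(nd) - 2L
    id2 <- id1 + 1L
    next_id <- next_id + 2L * nd
    events <- rbind(events, data.frame(
      kind = "division", generation = as.integer(generation),
      parent1 = pv, parent2 = NA_real_,
      child1 = c1, child2 = c2,
      parent1_id = langs$lineage_id[divide], parent2_id = NA_integer_,
      child1_id = id1, child2_id = id2))
    children <- new_languages(c(c1, c2), c(id1, id2))
  }

  out <- rbind(keep, children)
  rownames(out) <- NULL
  attr(out, "division_child") <- c(rep(FALSE, nrow(keep)),
                                   rep(TRUE, if (is.null(children)) 0 else nrow(children)))
  list(langs = out, events = events, next_id = next_id)
}

#' Language extinction
#'
#' Removes every language that no agent used this generation. Children
#' created by division in the same generation are exempt (their parent was
#' used). Membership is matched by lineage id against the communication log,
#' so the check is robust to the reordering done by change/division.
#'
#' @param langs Language population (possibly carrying the `division_child`
#'   attribute set by [apply_cultural_change()]).
#' @param log A `comm_log` for the current generation.
#' @param generation Generation number stamped on emitted events.
#' @return A list: `langs`, `events`.
#' @export
apply_extinction <- function(langs, log, generation = 0L) {
  if (nrow(langs) == 0) return(list(langs = langs, events = empty_events()))
  used_ids <- log$lang_lineage[unique(log$users$lang)]
  protected <- attr(langs, "division_child")
  if (is.null(protected)) protected <- rep(FALSE, nrow(langs))
  keep <- langs$lineage_id %in% used_ids | protected
  events <- empty_events()
  if (any(!keep)) {
    events <- data.frame(
      kind = "extinction", generation = as.integer(generation),
      parent1 = langs$pos[!keep], parent2 = NA_real_,
      child1 = NA_real_, child2 = NA_real_,
      parent1_id = langs$lineage_id[!keep], parent2_id = NA_integer_,
      child1_id = NA_integer_, child2_id = NA_integer_)
  }
  out <- langs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "division_child") <- NULL
  list(langs = out, events = events)
}

#' Language fusion
#'
#' While any two languages are closer than `Tf`, the closest pair (ties
#' broken by lower position) merges into a single language at its midpoint,
#' carrying a fresh lineage id. Greedy nearest-pair merging repeats until all
#' pairwise distances are >= `Tf`, so cascades terminate.
#'
#' @param langs Language population.
#' @param params A [sim_params()] object (uses `Tf`).
#' @param generation Generation number stamped on emitted events.
#' @param next_id Next free lineage identifier.
#' @return A list: `langs`, `events`, `next_id`.
#' @export
apply_fusion <- function(langs, params, generation = 0L, next_id = NULL) {
  if (is.null(next_id)) next_id <- max(0L, langs$lineage_id) + 1L
  events <- empty_events()
  if (nrow(langs) < 2) {
    return(list(langs = langs, events = events, next_id = next_id))
  }
  pos <- langs$pos
  id <- langs$lineage_id
  repeat {
    o <- order(pos)
    pos <- pos[o]; id <- id[o]
    if (length(pos) < 2) break
    gaps <- diff(pos)
    k <- which.min(gaps)  # first minimum = lowest-position tie-break
    if (gaps[k] >= params$Tf) break
    mid <- (pos[k] + pos[k + 1]) / 2
    events <- rbind(events, event_row(
      "fusion", generation,
      parent1 = pos[k], parent2 = pos[k + 1], child1 = mid,
      parent1_id = id[k], parent2_id = id[k + 1], child1_id = next_id))
    pos <- c(pos[-c(k, k + 1)], mid)
    id <- c(id[-c(k, k + 1)], next_id)
    next_id <- next_id + 1L
  }
  list(langs = new_languages(pos, id), events = events, next_id = next_id)
}
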
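## Plain-text run output: trace.csv, events.jsonl, params.json.

#' Write a run to disk
#'
#' Writes three plain-text files into `dir`:
#' \describe{
#'   \item{`trace.csv`}{one row per generation — `gen`, `mean_a`, `mean_p`,
#'     `mean_fitness`, `mean_lang_pos`, `n_langs`, `n_successes`.}
#'   \item{`events.jsonl`}{one cultural event per line (`kind`,
#'     `generation`, parent/child positions and lineage ids).}
#'   \item{`params.json`}{the resolved [sim_params()] (including the seed),
#'     plus the extinction generation if any.}
#' }
#'
#' @param trace A `coevo_trace`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "coevo_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trace$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "events.jsonl"), "w")
  on.exit(close(con))
  if (nrow(trace$events)) {
    jsonlite::stream_out(trace$events, con, verbose = FALSE, digits = NA)
  }
  jsonlite::write_json(
    c(unclass(trace$params),
      list(extinction_generation = trace$extinction_generation)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a run back from disk
#'
#' Inverse of [write_trace()]. The final populations are not serialised, so
#' `final_state` is `NULL` in the result.
#'
#' @param dir Directory written by [write_trace()].
#' @return A `coevo_trace`.
#' @export
read_trace <- function(dir) {
  trace <- utils::read.csv(file.path(dir, "trace.csv"))
  ef <- file.path(dir, "events.jsonl")
  events <- if (file.exists(ef) && file.size(ef) > 0) {
    ev <- jsonlite::stream_in(file(ef), verbose = FALSE)
    schema <- empty_events()
    for (col in names(schema)) {
      if (is.null(ev[[col]])) ev[[col]] <- NA
      # all-NA columns come back logical; restore the schema types
      mode_fn <- if (is.integer(schema[[col]])) as.integer
                 else if (is.numeric(schema[[col]])) as.numeric
                 else as.character
      ev[[col]] <- mode_fn(ev[[col]])
    }
    ev[names(schema)]
  } else empty_events()
  pj <- jsonlite::read_json(file.path(dir, "params.json"),
                            simplifyVector = TRUE)
  ext <- pj$extinction_generation
  pj$extinction_generation <- NULL
  params <- do.call(sim_params, pj)
  structure(list(trace = trace, events = events, params = params,
                 extinction_generation = if (is.null(ext) || is.na(ext))
                   NA_integer_ else as.integer(ext),
                 final_state = NULL),
            class = "coevo_trace")
}

#' Read a run configuration file
#'
#' JSON file mirroring [sim_params()] field for field; missing fields take
#' the package defaults, unknown fields are an error.
#'
#' @param path Path to a JSON configuration file.
#' @return A [sim_params()] object.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration fields: ",
                        paste(bad, collapse = ", "))
  do.call(sim_params, cfg)
}
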
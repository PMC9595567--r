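#' Write a population snapshot
#'
#' Tab-separated table with columns `id`, `cell_x`[, `cell_y`], `phi`
#' [, `anc`], preceded by comment lines recording the timestamp and the full
#' parameter set.
#'
#' @param state Population state data frame.
#' @param path Output path.
#' @param params Optional [sim_params()] recorded in the header.
#' @param t Timestamp (generations) recorded in the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path, params = NULL, t = attr(state, "t")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# altcolony snapshot t=%s", format(t)), con)
  if (!is.null(params)) {
    kv <- paste(config_keys, vapply(params[config_keys], format, character(1)),
                sep = "=", collapse = " ")
    writeLines(paste("#", kv), con)
  }
  if (!"id" %in% names(state)) state$id <- seq_len(nrow(state))
  cols <- intersect(c("id", "cell_x", "cell_y", "phi", "anc"), names(state))
  write.table(state[cols], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population snapshot written by [write_snapshot()]
#'
#' @param path Snapshot path.
#' @return The state data frame; the header timestamp is restored as
#'   attribute `t`.
#' @export
read_snapshot <- function(path) {
  first <- readLines(path, n = 1L)
  st <- read.delim(path, comment.char = "#")
  tm <- sub("^# altcolony snapshot t=", "", first)
  if (tm != first) attr(st, "t") <- as.numeric(tm)
  st
}

#' Write the time series of a run
#'
#' Columns `t`, `n`, `mean_phi`, `mean_phi_eff`, `cum_selection`,
#' `cum_drift`, `cum_bias`.
#'
#' @param run A `sim_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  kv <- paste(config_keys, vapply(run$params[config_keys], format, character(1)),
              sep = "=", collapse = " ")
  writeLines(paste("#", kv), con)
  write.table(run$series, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all outputs of a run to a directory
#'
#' Creates `series.tsv` and one `snapshot_<t>.tsv` per lineage boundary.
#'
#' @param run A `sim_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_series(run, file.path(dir, "series.tsv"))
  for (s in run$snapshots) {
    t <- attr(s, "t")
    write_snapshot(s, file.path(dir, sprintf("snapshot_%012.2f.tsv", t)),
                   params = run$params, t = t)
  }
  invisible(dir)
}

#' Read the snapshots of a run directory
#' @param dir Directory written by [write_run()].
#' @return List of snapshot data frames ordered by time.
#' @export
read_run_snapshots <- function(dir) {
  files <- sort(list.files(dir, pattern = "^snapshot_.*\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no snapshots found in ", dir)
  lapply(files, read_snapshot)
}
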
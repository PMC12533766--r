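# CSV interchange for trial tables, preference counts, draws and reports.
# Every artifact carries a commented metadata line with seed and content
# hash so a run can be traced end to end.

meta_line <- function(meta) {
  paste0("# lbaeff_meta ", jsonlite::toJSON(meta, auto_unbox = TRUE))
}

read_meta <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# lbaeff_meta ")) return(NULL)
  jsonlite::fromJSON(sub("^# lbaeff_meta ", "", first))
}

#' Write / read a trial table as CSV
#'
#' The documented header is `participant_id, group, trial_id, mode,
#' keyword_index, response, rt_seconds, kw1_correct, kw2_correct`; a
#' commented first line stores metadata (seed, content hash).  On reading,
#' the schema is validated, response times are checked positive, and the
#' serial-dependency context flags are recomputed from the response column
#' and cross-checked against the stored values; inconsistencies raise an
#' error naming the offending trials.  Unknown extra columns are kept with
#' a warning.
#'
#' @param data Trial table.
#' @param path File path.
#' @param meta Optional named list merged into the metadata line.
#' @return `write_trials` returns `path` invisibly; `read_trials` the
#'   validated trial table.
#' @export
write_trials <- function(data, path, meta = list()) {
  meta <- modifyList(list(artifact = "trials", hash = dataset_hash(data)), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_line(meta), con)
  write.csv(data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "trial_id", "mode",
                "keyword_index", "response", "rt_seconds", "kw1_correct",
                "kw2_correct")
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("trials file missing columns: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(x), required)
  if (length(extra)) warning("ignoring unknown columns: ",
                             paste(extra, collapse = ", "))
  bad_rt <- which(!is.finite(x$rt_seconds) | x$rt_seconds <= 0)
  if (length(bad_rt)) stop("non-positive response times at rows: ",
                           paste(head(bad_rt, 10L), collapse = ", "))
  if (!all(x$response %in% response_levels()))
    stop("unknown response categories in column 'response'")
  x$response <- factor(x$response, levels = response_levels())
  x$kw1_correct <- as.logical(x$kw1_correct)
  x$kw2_correct <- as.logical(x$kw2_correct)
  check_context_flags(x)
  attr(x, "meta") <- read_meta(path)
  x
}

# recompute kw1/kw2 context from the response column and compare
check_context_flags <- function(x) {
  key <- paste(x$participant_id, x$trial_id)
  corr <- x$response == "correct"
  kw1 <- corr[x$keyword_index == 1L][match(key, key[x$keyword_index == 1L])]
  kw2 <- corr[x$keyword_index == 2L][match(key, key[x$keyword_index == 2L])]
  bad <- (x$keyword_index >= 2L & (is.na(x$kw1_correct) | x$kw1_correct != kw1)) |
    (x$keyword_index == 3L & (is.na(x$kw2_correct) | x$kw2_correct != kw2))
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    ids <- unique(key[bad])
    stop("context flags inconsistent with responses for trials: ",
         paste(head(ids, 10L), collapse = "; "))
  }
  invisible(TRUE)
}

#' Write / read preference counts as CSV
#'
#' @param counts Preference-count table (`group`, `conversation`, `mode`,
#'   `count`).
#' @param path File path.
#' @param meta Optional metadata list.
#' @export
write_preference_counts <- function(counts, path, meta = list()) {
  validate_counts(counts, require_conversation = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_line(modifyList(list(artifact = "preference_counts"), meta)), con)
  write.csv(counts, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_preference_counts
#' @export
read_preference_counts <- function(path) {
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_counts(x, require_conversation = TRUE)
  attr(x, "meta") <- read_meta(path)
  x
}

#' Persist posterior draws as a long CSV plus JSON diagnostics
#'
#' Draws are stored one value per row (`chain`, `iteration`, `parameter`,
#' `value`); the diagnostics summary (split-Rhat, bulk/tail ESS, flags and
#' sampler metadata) is written alongside as JSON.  `read_draws` restores
#' the `[iteration, chain, parameter]` array.
#'
#' @param fit An `lba_fit` object (or a 3-d draws array).
#' @param path CSV path for the draws.
#' @param diagnostics_path Optional JSON path for the diagnostics summary.
#' @param parameters Subset of parameter names to persist (default: the
#'   group-level parameters; use `dimnames(fit$draws)[[3]]` for all).
#' @export
write_draws <- function(fit, path, diagnostics_path = NULL,
                        parameters = NULL) {
  a <- if (inherits(fit, "lba_fit")) fit$draws else fit
  if (is.null(parameters))
    parameters <- if (inherits(fit, "lba_fit")) fit$group_param_names
                  else dimnames(a)[[3]]
  a <- a[, , parameters, drop = FALSE]
  dd <- dim(a)
  long <- data.frame(
    chain = rep(rep(seq_len(dd[2]), each = dd[1]), times = dd[3]),
    iteration = rep(seq_len(dd[1]), times = dd[2] * dd[3]),
    parameter = rep(parameters, each = dd[1] * dd[2]),
    value = as.vector(a))
  meta <- list(artifact = "draws")
  if (inherits(fit, "lba_fit"))
    meta <- c(meta, list(seed = fit$config$seed, hash = fit$data_hash,
                         chains = dd[2], iterations = dd[1]))
  con <- file(path, "w")
  writeLines(meta_line(meta), con)
  write.csv(long, con, row.names = FALSE)
  close(con)
  if (!is.null(diagnostics_path)) {
    diag <- convergence_diagnostics(a)
    jsonlite::write_json(list(meta = meta, diagnostics = diag),
                         diagnostics_path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  long <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "iteration", "parameter", "value") %in% names(long)))
  pars <- unique(long$parameter)
  chains <- sort(unique(long$chain))
  iters <- sort(unique(long$iteration))
  a <- array(NA_real_, c(length(iters), length(chains), length(pars)),
             dimnames = list(NULL, paste0("chain", chains), pars))
  idx <- cbind(match(long$iteration, iters), match(long$chain, chains),
               match(long$parameter, pars))
  a[idx] <- long$value
  attr(a, "meta") <- read_meta(path)
  a
}
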
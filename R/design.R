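#' Specify the factorial design of a synthetic study
#'
#' Encodes the structure of the two-group, three-mode closed-set
#' speech-recognition study: each participant completes
#' `trials_per_mode * length(modes)` trials (20 x 3 = 60 by default), with
#' exactly `trials_per_mode` trials per presentation mode delivered in
#' seeded-random order, and selects `keywords_per_trial` keywords per
#' sentence.
#'
#' @param n_per_group Participants per group (default 50).
#' @param groups Ordered group labels; the reference group comes first.
#' @param modes Ordered presentation-mode labels.
#' @param trials_per_mode Trials per presentation mode (default 20).
#' @param keywords_per_trial Keywords selected per sentence (default 3).
#' @param conversations Conversation labels for the preference arm.
#' @param seed Integer seed controlling the trial-order permutation.
#' @return An object of class `lba_design_spec`.
#' @export
design_spec <- function(n_per_group = 50L,
                        groups = c("AH", "CI"),
                        modes = c("audio", "video", "captions"),
                        trials_per_mode = 20L,
                        keywords_per_trial = 3L,
                        conversations = c("A", "B", "C"),
                        seed = 1L) {
  if (n_per_group < 1 || trials_per_mode < 1 || keywords_per_trial < 1)
    stop("invalid design: counts must be positive integers")
  if (length(groups) < 1 || length(modes) < 1)
    stop("invalid design: need at least one group and one mode")
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 modes = modes, trials_per_mode = as.integer(trials_per_mode),
                 keywords_per_trial = as.integer(keywords_per_trial),
                 conversations = conversations, seed = as.integer(seed)),
            class = "lba_design_spec")
}

#' @export
print.lba_design_spec <- function(x, ...) {
  cat("Design:", length(x$groups), "groups x", x$n_per_group,
      "participants,", x$trials_per_mode, "trials per mode x",
      length(x$modes), "modes,", x$keywords_per_trial, "keywords/trial\n")
  cat("Total keyword slots:",
      length(x$groups) * x$n_per_group * x$trials_per_mode * length(x$modes) *
        x$keywords_per_trial, "\n")
  invisible(x)
}

#' Build the trial-level design table
#'
#' Expands a design specification into one row per keyword slot
#' (participant x trial x keyword), with a balanced, seeded-random
#' allocation of presentation modes to trials for every participant.
#' Identical seeds give byte-identical tables.
#'
#' @param spec An [design_spec()] object.
#' @return A data.frame with columns `participant_id`, `group`, `trial_id`,
#'   `mode`, `keyword_index`.
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "lba_design_spec"))
  n_modes <- length(spec$modes)
  trials <- spec$trials_per_mode * n_modes
  ids <- unlist(lapply(spec$groups, function(g)
    sprintf("%s%03d", g, seq_len(spec$n_per_group))))
  groups <- rep(spec$groups, each = spec$n_per_group)
  base_modes <- rep(spec$modes, each = spec$trials_per_mode)
  mode_by_part <- with_seed(spec$seed, {
    lapply(seq_along(ids), function(i) sample(base_modes))
  })
  n_part <- length(ids)
  kw <- spec$keywords_per_trial
  out <- data.frame(
    participant_id = rep(ids, each = trials * kw),
    group = rep(groups, each = trials * kw),
    trial_id = rep(rep(seq_len(trials), each = kw), times = n_part),
    mode = unlist(lapply(mode_by_part, function(m) rep(m, each = kw))),
    keyword_index = rep(seq_len(kw), times = n_part * trials),
    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}
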
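#' Generative population for synthetic cohorts
#'
#' Defines the true data-generating process: per-group mean vectors of the
#' 17 individual-level parameters (on the unconstrained scale), shared
#' between-subject scales and correlation matrix, and the contaminant
#' component.  The defaults qualitatively emulate the study setting:
#' near-ceiling performance for the acoustic-hearing (AH) reference group
#' in every mode, and mode-graded performance for the cochlear-implant (CI)
#' group (audio < video < captions), with a 2% lapse rate.
#'
#' Default generative values (constrained scale): AH correct drifts 3.0 in
#' all modes, CI correct drifts 1.8 / 2.1 / 2.4 (audio / video / captions),
#' all error drifts -0.25, boosts 0.4 (keyword 2) and 0.6 (keyword 3),
#' A = 0.8, b = 1.6, t0 = 0.3 s, lambda = 0.02, t_max = 10 s.  The error
#' drift and threshold were calibrated once, by quadrature of the race
#' density, so the group-mean accuracies reproduce the study's pattern
#' (near-ceiling AH performance in every mode; CI accuracy graded
#' audio < video < captions with roughly 20% audio-only errors); see the
#' methods vignette.
#'
#' @param group_means Named list of unconstrained 17-vectors, one per group.
#' @param scales Positive between-subject SDs (length 17).
#' @param correlation 17 x 17 correlation matrix (symmetric positive
#'   definite, unit diagonal).
#' @param contaminant_prop Lapse probability in `[0, 1]`.
#' @param t_max Upper bound of the contaminant RT distribution (seconds).
#' @return An object of class `lba_population`.
#' @export
true_population <- function(group_means = default_group_means(),
                            scales = default_scales(),
                            correlation = diag(17),
                            contaminant_prop = 0.02,
                            t_max = 10) {
  stopifnot(is.list(group_means), length(scales) == 17L,
            all(dim(correlation) == c(17L, 17L)))
  if (any(scales < 0)) stop("scales must be non-negative")
  if (contaminant_prop < 0 || contaminant_prop > 1)
    stop("contaminant_prop must lie in [0, 1]")
  if (t_max <= 0) stop("t_max must be positive")
  if (max(abs(correlation - t(correlation))) > 1e-12 ||
      max(abs(diag(correlation) - 1)) > 1e-12)
    stop("correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation must be positive definite")
  for (g in names(group_means)) stopifnot(length(group_means[[g]]) == 17L)
  structure(list(group_means = group_means, scales = as.numeric(scales),
                 correlation = correlation,
                 contaminant_prop = contaminant_prop, t_max = t_max),
            class = "lba_population")
}

#' @rdname true_population
#' @export
default_group_means <- function() {
  nm <- lba_param_names()
  mk <- function(correct) {
    p <- c(rep(c(NA, -0.25, -0.25, -0.25), 3), 0.4, 0.6, 0.8, 1.6, 0.3)
    p[c(1, 5, 9)] <- correct
    names(p) <- nm
    unconstrain_params(p)
  }
  list(AH = mk(c(3.0, 3.0, 3.0)), CI = mk(c(1.8, 2.1, 2.4)))
}

#' @rdname true_population
#' @export
default_scales <- function() {
  # moderate individual differences: drift SD 0.4, boosts 0.2, and 0.2 on
  # the log/shifted-log scales of A, b - A, t0 - 0.15
  c(rep(0.4, 12), 0.2, 0.2, 0.2, 0.2, 0.2)
}

#' Draw individual-level parameter vectors from the population
#'
#' Individuals' unconstrained 17-vectors are multivariate normal around the
#' group mean with covariance `diag(scales) %*% correlation %*% diag(scales)`;
#' the constrained scale is obtained through [constrain_params()], so every
#' draw satisfies `A > 0`, `b > A`, `t0 >= 0.150`.
#'
#' @param pop An [true_population()] object.
#' @param group Group label present in `pop$group_means`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return List with `unconstrained` and `constrained` `n x 17` matrices.
#' @export
draw_individual_parameters <- function(pop, group, n, seed = 1L) {
  stopifnot(inherits(pop, "lba_population"))
  mu <- pop$group_means[[group]]
  if (is.null(mu)) stop("unknown group: ", group)
  L <- tryCatch(t(chol(pop$correlation)),
                error = function(e) stop("correlation matrix is not positive definite"))
  z <- with_seed(seed, matrix(rnorm(n * 17L), n, 17L))
  u <- sweep(z %*% t(diag(pop$scales) %*% L), 2L, mu, "+")
  colnames(u) <- lba_param_names()
  list(unconstrained = u, constrained = constrain_params(u))
}
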
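# Synthetic participant-cohort generator: multivariate-normal draws of
# (F0, F0var, orienting latency, dwell index) with a prescribed correlation
# structure (Gaussian copula with normal marginals), plus inclusion flags.

COHORT_VARS <- c("f0_hz", "f0var_hz", "orienting_latency_ms", "dwell_index")

#' Specification of a synthetic participant cohort
#'
#' Defaults are the descriptive parameters of the neonatal (Tampere-like)
#' cohort: F0 463.45 (62.52) Hz, F0var 65.18 (26.10) Hz, orienting latency
#' 421.36 (53.41) ms, dwell index 0.73 (0.16).
#'
#' @param n_participants Cohort size.
#' @param cohort Cohort label (\code{"tampere"} or \code{"cape_town"}).
#' @param means,sds Named numeric vectors over \code{f0_hz}, \code{f0var_hz},
#'   \code{orienting_latency_ms}, \code{dwell_index}.
#' @param corr 4x4 correlation matrix over the same variables (symmetric
#'   positive semi-definite).
#' @param bout_start_fraction Fraction of recordings captured from the bout
#'   start.
#' @param ssri_fraction Fraction of participants with prenatal SSRI
#'   exposure.
#' @param seed RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_participants = 54L, cohort = "tampere",
                        means = c(f0_hz = 463.45, f0var_hz = 65.18,
                                  orienting_latency_ms = 421.36,
                                  dwell_index = 0.73),
                        sds = c(f0_hz = 62.52, f0var_hz = 26.10,
                                orienting_latency_ms = 53.41,
                                dwell_index = 0.16),
                        corr = diag(4), bout_start_fraction = 0.55,
                        ssri_fraction = 0, seed = 1L) {
  .assert(length(means) == 4L && length(sds) == 4L, "need 4 means and sds")
  .assert(all(dim(corr) == c(4L, 4L)), "corr must be 4x4")
  .assert(isTRUE(all.equal(corr, t(corr))), "corr must be symmetric")
  .assert(min(eigen(corr, symmetric = TRUE,
                    only.values = TRUE)$values) > -1e-8,
          "corr must be positive semi-definite")
  structure(list(
    n_participants = as.integer(n_participants), cohort = cohort,
    means = stats::setNames(as.numeric(means), COHORT_VARS),
    sds = stats::setNames(as.numeric(sds), COHORT_VARS),
    corr = corr, bout_start_fraction = bout_start_fraction,
    ssri_fraction = ssri_fraction, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Cape Town-like cohort specification
#'
#' Defaults: F0 475.34 (48.20) Hz, F0var 54.63 (21.49) Hz, orienting latency
#' 342.36 (72.47) ms, dwell index 0.56 (0.16); all recordings start at the
#' bout beginning, with a fraction of SSRI-exposed participants.
#'
#' @param n_participants Cohort size.
#' @param corr Correlation matrix as in \code{\link{cohort_spec}}.
#' @param seed RNG seed.
#' @param ... Further overrides passed to \code{\link{cohort_spec}}.
#' @return An object of class \code{cohort_spec}.
#' @export
cape_town_spec <- function(n_participants = 59L, corr = diag(4), seed = 1L,
                           ...) {
  cohort_spec(n_participants = n_participants, cohort = "cape_town",
              means = c(f0_hz = 475.34, f0var_hz = 54.63,
                        orienting_latency_ms = 342.36, dwell_index = 0.56),
              sds = c(f0_hz = 48.20, f0var_hz = 21.49,
                      orienting_latency_ms = 72.47, dwell_index = 0.16),
              corr = corr, bout_start_fraction = 1,
              ssri_fraction = 14 / 59, seed = seed, ...)
}

#' Generate a synthetic participant cohort
#'
#' Draws a latent multivariate normal with the specified correlation matrix,
#' scales marginals to the specified means/SDs, clips the dwell index to
#' \code{[0, 1]}, and assigns bout-start / SSRI flags by the specified
#' fractions.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A list with \code{participants} (data.frame:
#'   \code{participant_id}, \code{cohort}, \code{f0_hz}, \code{f0var_hz},
#'   \code{orienting_latency_ms}, \code{dwell_index},
#'   \code{bout_start_captured}, \code{ssri_exposed}) and \code{truth}
#'   (the spec, including the latent correlation matrix).
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  n <- spec$n_participants
  if (n == 0L) {
    empty <- data.frame(participant_id = character(0), cohort = character(0),
                        f0_hz = numeric(0), f0var_hz = numeric(0),
                        orienting_latency_ms = numeric(0),
                        dwell_index = numeric(0),
                        bout_start_captured = logical(0),
                        ssri_exposed = logical(0))
    return(list(participants = empty, truth = list(spec = spec)))
  }
  with_seed(spec$seed, {
    z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = spec$corr)
    if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
    vals <- sweep(sweep(z, 2L, spec$sds, `*`), 2L, spec$means, `+`)
    colnames(vals) <- COHORT_VARS
    vals[, "dwell_index"] <- pmin(pmax(vals[, "dwell_index"], 0), 1)
    n_bout <- round(spec$bout_start_fraction * n)
    n_ssri <- round(spec$ssri_fraction * n)
    participants <- data.frame(
      participant_id = sprintf("%s_%04d", toupper(substr(spec$cohort, 1, 2)),
                               seq_len(n)),
      cohort = spec$cohort,
      vals,
      bout_start_captured = sample(rep(c(TRUE, FALSE),
                                       c(n_bout, n - n_bout))),
      ssri_exposed = sample(rep(c(TRUE, FALSE), c(n_ssri, n - n_ssri)))
    )
    list(participants = participants, truth = list(spec = spec))
  })
}

#' Correlation matrix with one specified off-diagonal entry
#'
#' Convenience constructor for cohort simulations: identity except for the
#' correlation between two named variables.
#'
#' @param var1,var2 Variable names among \code{f0_hz}, \code{f0var_hz},
#'   \code{orienting_latency_ms}, \code{dwell_index}.
#' @param rho Correlation to install.
#' @return A 4x4 correlation matrix.
#' @export
corr_with <- function(var1 = "f0_hz", var2 = "dwell_index", rho = 0.5) {
  m <- diag(4)
  dimnames(m) <- list(COHORT_VARS, COHORT_VARS)
  m[var1, var2] <- m[var2, var1] <- rho
  m
}
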
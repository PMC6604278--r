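#' Specify one cell of a simulation design
#'
#' A simulation condition fixes the true population prevalence, the marginal
#' prevalence observed by each of the two error-prone sources, the tetrachoric
#' correlation between the sources, and the configuration of the binary
#' disease-marker panel that drives true disease status.
#'
#' The reference design crosses true prevalence \{0.10, 0.20\} with observed
#' source prevalences in \[0.05, 0.18\], source correlations \{0.65, 0.85\},
#' marker counts \{8, 16\}, mean marker correlations \{0.00, 0.20, 0.50\} and
#' exchangeable or unstructured marker-correlation patterns, but any valid
#' values are accepted.
#'
#' @param true_prev True population disease prevalence, in (0, 1).
#' @param obs_prev Length-2 vector of marginal prevalences for the two
#'   observed sources, each in (0, 1).
#' @param source_corr Target tetrachoric correlation between the two observed
#'   source indicators, in (-1, 1).
#' @param n_markers Number of binary disease markers (at least 2).
#' @param marker_corr Mean latent-scale correlation amongst markers, in [0, 1).
#' @param marker_corr_pattern `"exchangeable"` (all off-diagonals equal) or
#'   `"unstructured"` (off-diagonals vary around the mean).
#' @param population_size Individuals generated per replication.
#' @param marker_prevalences Optional vector of marker prevalences (length
#'   `n_markers`). When `NULL` they are drawn once per condition from
#'   U(0.05, 0.35) under the condition's seed.
#'
#' @return An object of class `"sim_condition"`.
#' @seealso [calibrate_accuracy()], [run_condition()]
#' @export
#' @examples
#' sim_condition(0.10, c(0.08, 0.07), source_corr = 0.85,
#'               n_markers = 16, marker_corr = 0)
sim_condition <- function(true_prev, obs_prev, source_corr, n_markers,
                          marker_corr = 0,
                          marker_corr_pattern = c("exchangeable", "unstructured"),
                          population_size = 10000,
                          marker_prevalences = NULL) {
  marker_corr_pattern <- match.arg(marker_corr_pattern)
  assert_prob(true_prev, "true_prev")
  stopifnot(length(obs_prev) == 2L)
  assert_prob(obs_prev, "obs_prev")
  if (!is.finite(source_corr) || abs(source_corr) >= 1) {
    stop("`source_corr` must lie in (-1, 1)", call. = FALSE)
  }
  stopifnot(n_markers >= 2, n_markers == round(n_markers))
  if (marker_corr < 0 || marker_corr >= 1) {
    stop("`marker_corr` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(population_size >= 1)
  if (!is.null(marker_prevalences)) {
    stopifnot(length(marker_prevalences) == n_markers)
    assert_prob(marker_prevalences, "marker_prevalences")
  }
  structure(
    list(true_prev = true_prev,
         obs_prev = as.numeric(obs_prev),
         source_corr = source_corr,
         n_markers = as.integer(n_markers),
         marker_corr = marker_corr,
         marker_corr_pattern = marker_corr_pattern,
         population_size = as.integer(population_size),
         marker_prevalences = marker_prevalences),
    class = "sim_condition"
  )
}

#' @export
#' @method print sim_condition
print.sim_condition <- function(x, ...) {
  cat("Simulation condition\n")
  cat(sprintf("  true prevalence      : %.3f\n", x$true_prev))
  cat(sprintf("  observed prevalences : %.3f, %.3f\n",
              x$obs_prev[1], x$obs_prev[2]))
  cat(sprintf("  source correlation   : %.2f (tetrachoric)\n", x$source_corr))
  cat(sprintf("  markers              : %d, mean corr %.2f (%s)\n",
              x$n_markers, x$marker_corr, x$marker_corr_pattern))
  cat(sprintf("  population size      : %d\n", x$population_size))
  invisible(x)
}
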
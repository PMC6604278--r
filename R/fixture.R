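#' Specification for a synthetic linked two-source cohort
#'
#' Describes a synthetic stand-in for a linked administrative/EMR cohort: a
#' true prevalence, per-source observed prevalences that straddle it (one
#' source over-capturing, one under-capturing), a target tetrachoric
#' correlation between the sources, and a block of socio-demographic and
#' comorbidity covariates. All values are synthetic defaults shaped like a
#' primary-care hypertension cohort; no real data are resampled.
#'
#' @param n Cohort size.
#' @param true_prev True disease prevalence.
#' @param obs_prev Length-2 observed source prevalences.
#' @param source_corr Target tetrachoric correlation between sources.
#' @param female Prevalence of the female indicator.
#' @param age_groups Named length-3 probability vector for the age groups
#'   (must sum to 1).
#' @param flags Named vector of binary comorbidity-flag prevalences.
#' @param flag_corr Exchangeable latent correlation amongst the covariates.
#' @param seed RNG seed.
#' @return An object of class `"cohort_fixture_spec"`.
#' @export
cohort_fixture_spec <- function(n = 68877, true_prev = 0.28,
                                obs_prev = c(0.31, 0.25),
                                source_corr = 0.90,
                                female = 0.567,
                                age_groups = c(`18-44` = 0.479,
                                               `45-64` = 0.381,
                                               `65+` = 0.140),
                                flags = c(diabetes = 0.093,
                                          depression = 0.160,
                                          obesity = 0.221,
                                          copd = 0.019,
                                          dementia = 0.016,
                                          chf = 0.008,
                                          cvd = 0.013,
                                          chd = 0.038,
                                          renal = 0.013,
                                          substance_abuse = 0.020),
                                flag_corr = 0.1, seed = 1) {
  stopifnot(n >= 100, length(obs_prev) == 2L, length(age_groups) == 3L,
            abs(sum(age_groups) - 1) < 1e-8, length(flags) >= 1)
  assert_prob(true_prev, "true_prev")
  assert_prob(obs_prev, "obs_prev")
  assert_prob(female, "female")
  assert_prob(flags, "flags")
  if (abs(source_corr) >= 1) stop("`source_corr` must lie in (-1, 1)",
                                  call. = FALSE)
  structure(list(n = as.integer(n), true_prev = true_prev,
                 obs_prev = obs_prev, source_corr = source_corr,
                 female = female, age_groups = age_groups, flags = flags,
                 flag_corr = flag_corr, seed = as.integer(seed)),
            class = "cohort_fixture_spec")
}

#' Generate a synthetic linked two-source cohort
#'
#' Builds a person-level table through the package's own copula machinery:
#' covariates (sex, age group, comorbidity flags) are generated from a latent
#' multivariate normal with a mild exchangeable correlation, true disease
#' status follows a logistic model on the covariates with the intercept
#' calibrated to the target prevalence, and the two source indicators apply
#' calibrated misclassification so that their marginal prevalences and
#' tetrachoric correlation match the specification.
#'
#' The `true_status` column is included because the cohort is synthetic; a
#' real linked cohort would not have it.
#'
#' @param spec A [cohort_fixture_spec()].
#' @return A data frame with columns `id`, `y_source1`, `y_source2`,
#'   `true_status`, `female`, `age_group`, and one 0/1 column per flag.
#' @export
generate_cohort_fixture <- function(spec = cohort_fixture_spec()) {
  stopifnot(inherits(spec, "cohort_fixture_spec"))
  k_flags <- length(spec$flags)
  k <- k_flags + 2L  # + female latent + age latent
  corr <- marker_correlation("exchangeable", spec$flag_corr, k)
  set.seed(spec$seed)
  z <- matrix(rnorm(spec$n * k), spec$n, k) %*% chol(corr)

  flags <- matrix(0L, spec$n, k_flags,
                  dimnames = list(NULL, names(spec$flags)))
  for (j in seq_len(k_flags)) {
    flags[, j] <- as.integer(z[, j] > qnorm(1 - spec$flags[j]))
  }
  female <- as.integer(z[, k_flags + 1L] > qnorm(1 - spec$female))
  age_lat <- z[, k_flags + 2L]
  cuts <- qnorm(cumsum(spec$age_groups))
  age_group <- cut(age_lat, breaks = c(-Inf, cuts[1:2], Inf),
                   labels = names(spec$age_groups))

  # logistic truth model: age dominates, flags contribute moderate log-odds
  design <- cbind(flags,
                  female = female,
                  age_45_64 = as.integer(age_group == names(spec$age_groups)[2]),
                  age_65p = as.integer(age_group == names(spec$age_groups)[3]))
  coefs <- c(seq(log(1.5), log(2.5), length.out = k_flags), -0.2, 1.2, 2.4)
  b0 <- calibrate_intercept(coefs, design, spec$true_prev, tol = 1e-5)
  truth <- generate_truth(structure(list(values = design), class = "marker_panel"),
                          disease_model(b0, coefs),
                          seed = spec$seed + 1L)

  cond <- sim_condition(spec$true_prev, spec$obs_prev, spec$source_corr,
                        n_markers = max(2L, k_flags),
                        population_size = spec$n)
  calib <- calibrate_accuracy(cond)
  sources <- apply_misclassification(truth, calib$acc1, calib$acc2,
                                     calib$dep, seed = spec$seed + 2L)
  out <- data.frame(id = seq_len(spec$n),
                    y_source1 = sources$y1,
                    y_source2 = sources$y2,
                    true_status = truth,
                    female = female,
                    age_group = as.character(age_group),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(flags))
}

#' Apply every estimator to a person-level cohort table
#'
#' Produces per-method prevalence estimates (single sources, OR, AND, RSSA
#' and optionally PSSA) for the whole table and, when `stratify_by` is given,
#' within each stratum of a categorical column.
#'
#' @param table Data frame with two binary source columns.
#' @param source_cols Names of the two source columns.
#' @param assumed [accuracy_pair()] for the RSSA correction.
#' @param methods Methods to run.
#' @param stratify_by Optional name of a categorical column.
#' @param pssa_covariates Character vector of covariate columns for the PSSA
#'   model (factors are expanded to indicators); required when `"pssa"` is
#'   requested.
#' @param pssa_control List with `n_iter`, `burn_in`, `n_chains` for PSSA.
#' @param B Bootstrap resamples for the RSSA interval.
#' @param seed RNG seed.
#' @return Data frame with columns `stratum`, `method`, `point`, `ci_low`,
#'   `ci_high`, `ci_method`, `n`.
#' @export
estimate_all <- function(table, source_cols = c("y_source1", "y_source2"),
                         assumed = default_assumed_accuracy(),
                         methods = c("source1", "source2", "or", "and",
                                     "rssa"),
                         stratify_by = NULL, pssa_covariates = NULL,
                         pssa_control = list(n_iter = 2000, burn_in = 500,
                                             n_chains = 2),
                         B = 999, seed = 1) {
  stopifnot(all(source_cols %in% names(table)))
  methods <- match.arg(methods,
                       c("source1", "source2", "or", "and", "rssa", "pssa"),
                       several.ok = TRUE)
  if ("pssa" %in% methods && is.null(pssa_covariates)) {
    stop("`pssa_covariates` must name the covariate columns when PSSA is requested",
         call. = FALSE)
  }
  if (!is.null(pssa_covariates) &&
      !all(pssa_covariates %in% names(table))) {
    missing_cols <- setdiff(pssa_covariates, names(table))
    stop(sprintf("covariate column(s) not found: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  run_block <- function(df, stratum) {
    s <- observed_sources(df[[source_cols[1]]], df[[source_cols[2]]])
    rows <- list()
    for (m in methods) {
      est <- switch(m,
        source1 = estimate_source(s, 1),
        source2 = estimate_source(s, 2),
        or = estimate_or(s),
        and = estimate_and(s),
        rssa = estimate_rssa(s, assumed, B = B, seed = seed),
        pssa = {
          mm <- model.matrix(
            ~ . - 1,
            data = as.data.frame(lapply(df[pssa_covariates], function(v) {
              if (is.character(v)) factor(v) else v
            })))
          fit <- pssa(s$y1, s$y2, mm,
                      n_iter = pssa_control$n_iter,
                      burn_in = pssa_control$burn_in,
                      n_chains = pssa_control$n_chains, seed = seed)
          posterior_prevalence(fit)
        })
      rows[[m]] <- cbind(stratum = stratum, as.data.frame(est))
    }
    do.call(rbind, rows)
  }

  out <- run_block(table, "overall")
  if (!is.null(stratify_by)) {
    stopifnot(stratify_by %in% names(table))
    for (lev in unique(table[[stratify_by]])) {
      out <- rbind(out,
                   run_block(table[table[[stratify_by]] == lev, , drop = FALSE],
                             paste0(stratify_by, "=", lev)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write estimates as delimited text and JSON
#'
#' @param estimates Data frame from [estimate_all()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Paths written, invisibly.
#' @export
write_estimates <- function(estimates, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(estimates, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON export", call. = FALSE)
    }
    jsonlite::write_json(estimates, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(c(csv_path, json_path))
}
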
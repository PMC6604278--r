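# Internal validation and seeding helpers.

assert_prob <- function(x, name, open_low = TRUE, open_high = TRUE) {
  lo_ok <- if (open_low) x > 0 else x >= 0
  hi_ok <- if (open_high) x < 1 else x <= 1
  if (!all(is.finite(x)) || !all(lo_ok) || !all(hi_ok)) {
    stop(sprintf("`%s` must be a proportion in %s0, 1%s", name,
                 if (open_low) "(" else "[", if (open_high) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

assert_binary <- function(x, name) {
  if (!all(x %in% c(0L, 1L))) {
    stop(sprintf("`%s` must contain only 0/1 values", name), call. = FALSE)
  }
  invisible(x)
}

# Deterministic 31-adic string hash reduced mod (2^31 - 1), so the result is a
# valid R integer seed.  Exact in double arithmetic because intermediate values
# stay below 2^53.
stable_hash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Per-condition seed: base seed offset by a stable hash of the condition fields,
# so every grid cell is independently reproducible.
condition_seed <- function(base_seed, condition) {
  h <- stable_hash(
    format(condition$true_prev, digits = 12),
    format(condition$obs_prev, digits = 12),
    format(condition$source_corr, digits = 12),
    condition$n_markers,
    format(condition$marker_corr, digits = 12),
    condition$marker_corr_pattern
  )
  as.integer((as.numeric(base_seed) + h) %% 2147483647)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
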
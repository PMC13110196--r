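# internal helpers shared across modules

# deterministic 31-bit seed derived from a base seed plus arbitrary labels,
# so every simulation stream is independently reproducible
mix_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(format(x, digits = 15), collapse = ","),
                  character(1))
  h <- 7
  for (b in utf8ToInt(paste(parts, collapse = "|"))) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}

# impute missing matrix entries with the per-column (per-visit) median;
# a column with no observed value falls back to the grand median, then 0
impute_visit_median <- function(m) {
  if (!anyNA(m)) {
    return(m)
  }
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  grand <- stats::median(m, na.rm = TRUE)
  if (!is.finite(grand)) grand <- 0
  med[!is.finite(med)] <- grand
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- med[idx[, 2]]
  m
}

stopifnot_probability <- function(p, arg) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    rlang::abort(
      sprintf("`%s` must lie in [0, 1]; got %s", arg,
              format(p[bad][1], digits = 6)),
      class = "sitespotter_config_error"
    )
  }
  invisible(p)
}
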
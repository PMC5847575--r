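# internal helpers shared across modules

# sample CV (%) on the linear scale; NA when fewer than 2 finite values
cv_percent <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * sd(x) / m
}

# closed-form linear-scale CV of a log2-normal variable with log2 SD `sigma`
lognormal_cv <- function(sigma_log2) {
  sqrt(exp((sigma_log2 * log(2))^2) - 1)
}

# log2-scale SD that yields a given linear-scale CV
cv_to_sigma_log2 <- function(cv) {
  sqrt(log(1 + cv^2)) / log(2)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
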
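# Internal helpers: condition classes and seeded evaluation.

tf_error <- function(msg, class) {
  stop(structure(
    class = c(class, "tf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(field, msg) {
  tf_error(sprintf("invalid `%s`: %s", field, msg), "tf_config_error")
}

validation_error <- function(msg) tf_error(msg, "tf_validation_error")

insufficient_data_error <- function(msg) {
  tf_error(msg, "tf_insufficient_data_error")
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# round() uses banker's rounding; reported percentages round half away from zero
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
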
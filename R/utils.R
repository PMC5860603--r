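# internal helpers shared across modules

# Deterministic child seed from a master seed plus a stream name.
# Polynomial string hash modulo a prime < 2^31 so adding instances or
# rounds never perturbs other streams.
derive_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), as.character, ""), collapse = ".")
  h <- as.double(as.integer(master) %% 2147483629L)
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483629
  as.integer(h) + 1L
}

# elementwise log(exp(a) + exp(b)), -Inf-safe
lse_pair <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[m == -Inf] <- -Inf
  out
}

# log-sum-exp across the columns of a matrix (small column count)
lse_cols <- function(x) {
  out <- x[, 1L]
  if (ncol(x) > 1L)
    for (j in 2:ncol(x)) out <- lse_pair(out, x[, j])
  out
}

fmt_int <- function(x) formatC(x, format = "d")

# full-precision decimal rendering that survives as.numeric() bit-exactly
fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) {
  stop(structure(class = c("saga_usage_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}
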
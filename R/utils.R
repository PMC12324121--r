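# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# cheap deterministic fingerprint for run logs (not cryptographic)
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 1000000007
  sprintf("%09d", h)
}

# validate a scalar numeric argument, erroring with the parameter name
check_scalar <- function(x, name, lo = -Inf, hi = Inf, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  ok <- if (open) x > lo && x < hi else x >= lo && x <= hi
  if (!ok)
    stop(sprintf("'%s' = %g is outside its allowed range [%g, %g]%s",
                 name, x, lo, hi, if (open) " (open)" else ""), call. = FALSE)
  invisible(x)
}

# format doubles so that read.csv() recovers them bit-exactly; only
# originally-character columns are quoted (colClasses-driven re-reads choke
# on quoted numerics)
write_csv_exact <- function(df, path) {
  out <- df
  quote_cols <- which(vapply(out, is.character, logical(1)))
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE,
                   quote = if (length(quote_cols)) quote_cols else FALSE,
                   na = "NA")
}
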
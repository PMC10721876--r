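# Internal helpers: deterministic seed mixing, config hashing, atomic writes.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 31-bit multiplicative mix; all arithmetic stays below 2^53 so the result is
# exact in doubles on every platform.  Used to derive independent sub-seeds
# from (seed, index...) tuples: any model / chain / residue / cell is
# reproducible in isolation.
.MIX_MOD <- 2147483647

mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 17
  for (p in parts) {
    stopifnot(is.finite(p))
    h <- (h * 31 + (as.numeric(p) %% .MIX_MOD)) %% .MIX_MOD
  }
  as.integer(h)
}

# Polynomial rolling hash over a character string, hex digest.  Small,
# dependency-free config fingerprint for output-file headers (not
# cryptographic).  Modulus 2^31-1 keeps every intermediate below 2^53, so the
# digest is exact and platform independent.
config_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261 %% .MIX_MOD
  for (b in bytes) {
    h <- ((h + b) * 131) %% .MIX_MOD
  }
  sprintf("%08x", as.integer(h))
}

# Write lines atomically: write to a temp file in the same directory, then
# rename.  Failed commands never leave partial output behind.
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop("could not write output file: ", path, call. = FALSE)
  }
  invisible(path)
}

# Data-frame rows as TSV strings; doubles at full round-trip precision.
tsv_rows <- function(df) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.15g", col) else as.character(col)
  })
  do.call(paste, c(cols, sep = "\t"))
}

stop_validation <- function(...) {
  cond <- structure(
    class = c("fibrilthread_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  )
  stop(cond)
}
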
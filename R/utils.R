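# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Normalize a free-text survey response label for tolerant matching:
# lowercase, unify unicode dashes to "-", drop "$", ",", ".", collapse
# whitespace.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("–|—|‒|‐", "-", x)
  x <- gsub("[$,.]", "", x)
  x <- gsub("\\s+", " ", x)
  x <- gsub(" ?- ?", "-", x)
  x
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used for the run manifest's config fingerprint (no external digest
# dependency needed for a non-cryptographic fingerprint).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor the low byte only (b < 256), keeping h a double below 2^32
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b %% 256))
    # multiply by 16777619 mod 2^32 without integer overflow
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministically derive a stage seed (< 2^31) from a run seed and a
# stage label, so pipeline stages are isolated but reproducible.
derive_seed <- function(seed, stage) {
  h <- strtoi(substr(fnv1a32(paste0(seed, "/", stage)), 1, 7), base = 16L)
  (as.integer(h) + as.integer(seed %% 1000L)) %% .Machine$integer.max
}

# Check a square matrix for symmetry + positive semi-definiteness.
check_psd <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_named("%s must be a square matrix", name)
  }
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop_named("%s must be symmetric", name)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev))) {
    stop_named("%s is not positive semi-definite (smallest eigenvalue %.3g)",
               name, min(ev))
  }
  invisible(TRUE)
}
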
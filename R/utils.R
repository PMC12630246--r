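# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Presentation rounding used throughout: ties round away from zero
#' (2.675 -> 2.68 at 2 digits), unlike [base::round()]'s round-half-even.
#' All comparisons and signal logic use full precision; this is applied
#' only when a value is printed or reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs binary-representation error (e.g. 2.675 * 100
  # = 267.49999...); harmless at the magnitudes handled here
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- list-in-cell serialization -------------------------------------------
# Multi-valued fields (drugs, reactions, outcomes) live in one CSV cell,
# joined with "|"; literal "|" and "\" inside an element are backslash-escaped.

join_listcell <- function(x) {
  if (length(x) == 0) return("")
  x <- ifelse(is.na(x), "", x)
  paste(gsub("([\\\\|])", "\\\\\\1", x), collapse = "|")
}

split_listcell <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  if (!grepl("\\\\", s)) return(strsplit(s, "|", fixed = TRUE)[[1]])
  # slow path only when escapes are present
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  cur <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      cur <- c(cur, chars[i + 1L])
      i <- i + 2L
    } else if (ch == "|") {
      out <- c(out, paste(cur, collapse = ""))
      cur <- character(0)
      i <- i + 1L
    } else {
      cur <- c(cur, ch)
      i <- i + 1L
    }
  }
  c(out, paste(cur, collapse = ""))
}

# 32-bit FNV-1a over a string; used for run-manifest input fingerprints.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply split to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

stop_pvror <- function(...) stop(sprintf(...), call. = FALSE)
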
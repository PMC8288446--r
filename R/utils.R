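# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded simulator calls do not perturb the session
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage / per-species substream seed from a root seed, kept
# below 2^31 so it is a valid R integer.
substream_seed <- function(seed, stage, index = 0L) {
  (as.numeric(seed) * 1009 + stage * 97003 + index * 131) %% 2147483647
}

# Sequences are stored as integer vectors: 1=A, 2=C, 3=G, 4=T, 0=N/uncalled.
seq_to_int <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) x <- strsplit(x, "")[[1L]]
  out <- match(toupper(x), BASES)
  out[is.na(out)] <- 0L
  as.integer(out)
}

int_to_seq <- function(x, collapse = TRUE) {
  ch <- c("N", BASES)[x + 1L]
  if (collapse) paste(ch, collapse = "") else ch
}

# Lower-triangle values of a square matrix (excluding the diagonal).
lower_tri <- function(m) m[lower.tri(m)]

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
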
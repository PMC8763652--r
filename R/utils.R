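## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers do not
#' disturb the caller's RNG stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a reproducible child seed from a parent seed and a label.
## Keeps results below .Machine$integer.max (R integers are 32-bit).
child_seed <- function(seed, label) {
  u <- utf8ToInt(as.character(label))
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 69069 + h) %% 2147483629)
}

stop_mrd <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_mrd(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x <= 1

#' Encode integers as fixed-length DNA barcodes
#'
#' Maps non-negative integers to unique base-4 DNA strings; used to mint
#' collision-free UMIs in the read simulator.
#' @param i Vector of non-negative integers.
#' @param width Barcode length in bases (default 10, enough for 4^10 ids).
#' @return Character vector of DNA barcodes.
#' @keywords internal
int_to_umi <- function(i, width = 10L) {
  bases <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = length(i), ncol = width)
  x <- as.numeric(i)
  for (k in seq_len(width)) {
    out[, width - k + 1L] <- bases[(x %% 4) + 1L]
    x <- x %/% 4
  }
  apply(out, 1L, paste0, collapse = "")
}

## stderr logging with a stage prefix, silenced via options(mrdtrace.quiet=TRUE)
log_msg <- function(stage, fmt, ...) {
  if (isTRUE(getOption("mrdtrace.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
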
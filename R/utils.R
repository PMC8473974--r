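# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All generators in the package draw their randomness from sub-seeds derived
#' deterministically from one master seed, so a single integer reproduces a
#' whole pipeline run. Kept below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param offset integer stream offset; distinct offsets give distinct streams.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m) * 69069 + (offset %% m) * 1234567 + 12345
  as.integer(s %% m)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a filter audit trail
#'
#' An audit records, for each rule of a filter cascade in order, how many
#' records entered, were removed, and survived. Conservation
#' (`n_out == n_in - n_removed`, and each step's `n_in` equals the previous
#' step's `n_out`) is checked at construction.
#'
#' @param rules character vector of rule names, in application order.
#' @param n_in,n_removed integer vectors parallel to `rules`.
#' @return a `filter_audit` data frame with columns
#'   `rule`, `n_in`, `n_removed`, `n_out`.
#' @export
filter_audit <- function(rules, n_in, n_removed) {
  stopifnot(length(rules) == length(n_in), length(n_in) == length(n_removed))
  n_in <- as.integer(n_in); n_removed <- as.integer(n_removed)
  n_out <- n_in - n_removed
  if (any(n_removed < 0) || any(n_out < 0))
    stop("filter_audit: negative counts")
  if (length(rules) > 1L && !all(n_in[-1L] == n_out[-length(n_out)]))
    stop("filter_audit: step inputs do not chain (n_in[k+1] != n_out[k])")
  out <- data.frame(rule = as.character(rules), n_in = n_in,
                    n_removed = n_removed, n_out = n_out,
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_audit", "data.frame")
  out
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filter audit (", nrow(x), " rules): ",
      if (nrow(x)) x$n_in[1L] else 0L, " in -> ",
      if (nrow(x)) x$n_out[nrow(x)] else 0L, " out\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# Stop unless all names in `need` are columns of data frame `df`.
check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s",
                 what, paste(miss, collapse = ", ")))
  invisible(df)
}

# Genotype call code sets (diploid, intergenomic 5-dosage, no-call).
DIPLOID_CODES <- c("AA", "AB", "BB")
TETRA_CODES   <- c("AAAA", "AAAB", "AABB", "ABBB", "BBBB")
ALL_CALL_CODES <- c(DIPLOID_CODES, TETRA_CODES, "NC")
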
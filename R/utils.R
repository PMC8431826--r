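# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  Every stochastic operation in the package funnels through
# this so that explicit seeds fully determine results.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stream of sub-seeds, kept strictly below 2^31 so they are
# representable as R integers.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(offset) * 15485863) %% 2147483629) + 1L
}

# repr-faithful float formatting: 17 significant digits round-trip any
# double bit-identically through as.numeric().
format_full <- function(x) sprintf("%.17g", x)

# Write a data.frame as a headered TSV with full-precision numerics and no
# quoting, so repeated runs are byte-identical.
write_tsv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    if (is.factor(out[[j]])) out[[j]] <- as.character(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

is_square_numeric <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

check_symmetric <- function(A, tol, what = "matrix") {
  asym <- max(abs(A - t(A)))
  if (asym > tol) {
    stop(sprintf("%s is not symmetric (max asymmetry %.3g exceeds tolerance %.3g)",
                 what, asym, tol), call. = FALSE)
  }
  (A + t(A)) / 2
}
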
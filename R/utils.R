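# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(..., call. = FALSE)

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Derive a stream of child seeds from one master seed
#'
#' Used so that every stochastic stage of a simulation gets its own
#' reproducible seed while the caller supplies a single integer.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- local_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

local_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run an expression with a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- local_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Variance of a standard normal truncated to (qnorm(lo), qnorm(hi)).
truncnorm_var <- function(lo, hi) {
  a <- stats::qnorm(lo)
  b <- stats::qnorm(hi)
  z <- hi - lo
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  mu <- (da - db) / z
  1 + (a * da - b * db) / z - mu^2
}

chrom_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
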
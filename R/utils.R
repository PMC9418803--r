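# Internal helpers shared across modules.

ALLELES <- c("A", "C", "G", "T")

invlogit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] that passes through when `seed` is
#' `NULL` (the expression then consumes the caller's RNG stream, which lets
#' nested generators stay reproducible under one outer seed).
#' @noRd
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != round(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  }
}

check_closed <- function(p, tol = 1e-6, name = "profile") {
  if (any(p < 0)) stop(sprintf("%s has negative abundances", name), call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("%s is not closed (abundances must sum to 1)", name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Close (normalise) a non-negative vector to sum to one
#' @noRd
close_composition <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot close an all-zero composition", call. = FALSE)
  x / s
}

# Vectorised multinomial sampler over alignment positions: n is an integer
# vector of per-position totals, prob a 4 x L column-stochastic matrix.
# Sequential binomial thinning keeps everything vectorised over L.
rmultinom_positions <- function(n, prob) {
  L <- length(n)
  stopifnot(ncol(prob) == L, nrow(prob) == 4L)
  counts <- matrix(0L, nrow = 4L, ncol = L)
  remaining <- as.integer(n)
  cum <- rep(0, L)
  for (a in 1:3) {
    q <- prob[a, ] / (1 - cum)
    q[!is.finite(q) | q < 0] <- 0
    q[q > 1] <- 1
    draw <- rbinom(L, remaining, q)
    counts[a, ] <- draw
    remaining <- remaining - draw
    cum <- cum + prob[a, ]
  }
  counts[4L, ] <- remaining
  rownames(counts) <- ALLELES
  counts
}
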
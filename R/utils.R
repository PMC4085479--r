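#' @keywords internal
"_PACKAGE"

#' @importFrom stats dlnorm plnorm qlnorm dnorm pnorm rnorm runif rexp median sd var
#'   optim glm.fit binomial quantile prcomp setNames cov complete.cases
#'   lm coef reshape
#' @importFrom utils head tail read.csv write.csv combn modifyList
NULL

# Trapezoidal integral of y over (possibly non-uniform) grid t.
trapz_int <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoidal integral, same length as input, starting at 0.
cumtrapz_int <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2))
}

# Round half away from zero to `digits` decimals.  A small epsilon guards
# against values such as (0.80 + 0.81)/2 landing a hair below the half due
# to binary representation.
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Derive a reproducible sub-seed from a master seed and stream labels
#'
#' Mixes a master seed with arbitrary labels (numbers or strings) into a
#' 31-bit integer, so that nested generators (per subject, per task, per
#' trial) never share an RNG stream while remaining fully determined by
#' the master seed.
#'
#' @param master integer master seed.
#' @param ... stream labels (numeric or character).
#' @return an integer seed in \[1, 2^31).
#' @export
derive_seed <- function(master, ...) {
  parts <- c(master, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 69069 + v * 12345 + 1) %% 2147483629
  }
  as.integer(h %% 2147483563) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
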
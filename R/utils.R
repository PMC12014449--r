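# Internal helpers: input validation and deterministic seed derivation.

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single finite positive number, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single finite non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    stop(sprintf("'%s' must be a fraction in %s0, 1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible substream seed from a master seed and a key
#'
#' Hashes a character key (e.g. `"chili|30|children|C"`) together with a
#' master integer seed into an integer in `[1, 2^31 - 2]`. Used so that every
#' scenario draws from its own stream: adding or reordering scenarios never
#' perturbs another scenario's random numbers.
#'
#' @param master_seed single integer master seed.
#' @param key character scalar identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(key), length(key) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  h <- (h * 48271) %% m
  as.integer((abs(master_seed) %% m + h) %% (m - 1) + 1)
}

# round half away from zero, matching how the source tables print values
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
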
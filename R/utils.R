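#' Derive a reproducible child seed from a master seed
#'
#' One master seed expands into independent per-stage streams (haplotype pool,
#' drift, family structure, per-replicate traits, samplers) so that each stage
#' is individually reproducible. Child seeds stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param stage stage label (character) or integer offset.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  # Weyl-style mixing, kept inside the positive 32-bit integer range
  x <- (as.double(seed) * 2654435761 + as.double(stage) * 40503 + 97) %% 2147483629
  as.integer(x) + 1L
}

#' Scaled inverse chi-square sampler
#'
#' Draws from scale * df / chisq(df), the conjugate posterior family for
#' normal variances.
#'
#' @param n number of draws.
#' @param df degrees of freedom (> 0).
#' @param scale scale parameter (> 0).
#' @return numeric vector of draws.
#' @export
rinvchisq <- function(n, df, scale) {
  stopifnot(df > 0, scale >= 0)
  df * scale / stats::rchisq(n, df)
}

# internal: stop unless x is a single finite number in (lo, hi) / [lo, hi]
check_scalar <- function(x, lo = -Inf, hi = Inf, name = deparse(substitute(x)),
                         open_lo = FALSE, open_hi = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must be a single finite value in %s%s, %s%s",
                        name, if (open_lo) "(" else "[", format(lo),
                        format(hi), if (open_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}
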
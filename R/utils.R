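# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators are pure functions of their
# seed argument.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_proportion <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(sprintf("`%s` must be a single number in [0, 1]", name))
  if (open && (x <= 0 || x >= 1))
    stop_arg(sprintf("`%s` must lie strictly in (0, 1)", name))
  if (!open && (x < 0 || x > 1))
    stop_arg(sprintf("`%s` must lie in [0, 1]", name))
  as.numeric(x)
}

#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}: the proportion of
#' phenotypic variance attributable to additive genetic variance.
#'
#' @param sigma_a2 Additive genetic variance (must be >= 0).
#' @param sigma_e2 Residual variance (must be >= 0, with a positive total).
#' @return Numeric heritability in `[0, 1]`; vectorised over its arguments.
#' @examples
#' heritability(10.88, 41.71) # rib eye area, ~0.20
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0) || any(sigma_a2 + sigma_e2 <= 0))
    stop_arg("variance components must be non-negative with a positive sum")
  sigma_a2 / (sigma_a2 + sigma_e2)
}
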
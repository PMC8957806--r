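#' @importFrom stats aggregate as.formula binomial coef glm pchisq pnorm
#'   predict qnorm quantile rbinom rexp rnorm runif sd setNames t.test var
#' @importFrom utils head
NULL

# Per-stage substreams derived from one user-facing seed, so a stage can be
# regenerated without replaying the stages before it. Offsets are arbitrary
# but fixed; results stay below 2^31 - 1.
.stage_offsets <- c(
  genotypes = 101L, effects = 211L, sumstats = 307L,
  phenotype = 401L, onset = 503L, pipeline = 601L
)

substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, stage %in% names(.stage_offsets))
  as.integer((as.numeric(seed) * 7919 + .stage_offsets[[stage]]) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name, open_left = TRUE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok)
    stop2(sprintf("`%s` must be a single value in %s0,1%s, got %s",
                  name, if (open_left) "(" else "[",
                  if (open_right) ")" else "]", format(x)))
  invisible(x)
}
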
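# Internal helpers shared across modules.

#' Derive a stage seed from a master seed
#'
#' Stage seeds are derived by stable string hashing of the stage name, so that
#' adding or reordering pipeline stages never shifts another stage's random
#' stream. The hash is a plain polynomial rolling hash over the UTF-8 bytes of
#' `stage`, folded into the 31-bit signed-integer range R requires of seeds.
#'
#' @param master_seed Integer master seed.
#' @param stage Character scalar naming the consumer of the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer((abs(master_seed) + h) %% m)
}

# run `expr` under a temporary RNG state seeded from (master, stage)
with_stage_seed <- function(master_seed, stage, expr) {
  withr::with_seed(derive_seed(master_seed, stage), expr)
}

# numeric scalar check with informative error
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "toposcreen_config_error")
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "toposcreen_config_error")
  }
  invisible(x)
}

# does `b` divide `a` to within floating-point slack?
divides <- function(a, b, tol = 1e-9) {
  r <- a / b
  abs(r - round(r)) < tol
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# require a set of columns, error naming the first one missing
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column `%s`.", what, missing[[1]]),
          class = "toposcreen_schema_error")
  }
  invisible(df)
}
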
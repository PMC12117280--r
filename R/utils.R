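`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed plus an arbitrary tag sequence to an
#' integer seed below 2^31, so that every stochastic stage of a pipeline can
#' receive its own stream without manual bookkeeping.
#'
#' @param seed Integer master seed.
#' @param ... Tags (characters or numbers) identifying the consumer.
#' @return A single integer seed in `[1, 2147483628]`.
#' @export
#' @examples
#' derive_seed(42, "arm")
#' derive_seed(42, "repeat", 3, "fold", 7)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "::")
  h <- abs(seed) %% 2147483629
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h %% 2147483628 + 1)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_binary01 <- function(x) all(x[!is.na(x)] %in% c(0, 1))
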
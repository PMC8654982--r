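#' @useDynLib revscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pnorm pf pt cor lm p.adjust rnorm rbinom runif
#'   setNames aggregate coef fisher.test t.test model.matrix qnorm var sd
#' @importFrom utils read.delim write.table head modifyList
NULL

# stop() wrapper producing classed conditions so callers can distinguish
# validation failures from computation failures
rs_error <- function(msg, class) {
  stop(structure(
    class = c(class, "revscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

rs_config_error <- function(msg) rs_error(msg, "revscreen_config_error")
rs_validation_error <- function(msg) rs_error(msg, "revscreen_validation_error")

# stage-tagged log line on stderr
rs_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Stable sub-stream seed from entity labels
#'
#' Derives a deterministic 31-bit seed from a base seed and an arbitrary set
#' of string labels, so that per-entity random draws do not depend on the
#' order in which entities are processed. Uses a polynomial rolling hash of
#' the UTF-8 bytes.
#'
#' @param seed base integer seed.
#' @param ... character or numeric labels identifying the sub-stream.
#' @return an integer in `[0, 2^31 - 1]`.
#' @keywords internal
stable_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# run expr with a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
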
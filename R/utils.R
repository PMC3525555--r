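#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 imap keep
NULL

# Consistent error classes so callers can condition on failure modes.
stop_coaldelim <- function(msg, class) {
  abort(msg, class = c(class, "coaldelim_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a private RNG stream so simulators are reproducible
# without disturbing the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
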
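#' Derive a child random seed from a master seed and a stream label
#'
#' All stochastic stages draw their seed from one user-supplied integer via
#' this deterministic hash, so regenerating a single subject or trial does not
#' disturb the random stream of any other stage.
#'
#' @param seed master integer seed.
#' @param label character stream label, e.g. `"cohort"` or
#'   `"S00012/EF/trial2"`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' child_seed(1, "cohort")
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label),
            length(label) == 1)
  m <- 2147483647 # 2^31 - 1, keeps exact double arithmetic below 2^53
  h <- abs(as.integer(seed)) %% m
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(h)
}
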
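#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Currency is handled internally as integer milli-euros (1/1000 EUR) so that
# sums over sub-cent unit prices stay exact; rounding to cents happens only
# at the reporting boundary.

eur_to_me <- function(x) {
  stopifnot(is.numeric(x))
  round(x * 1000)
}

me_to_eur <- function(me) me / 1000

#' Round a currency amount to cents
#'
#' Rounds euros to two decimals using round-half-to-even on the exact
#' milli-euro representation, so that amounts such as 140.745 round the way
#' integer cent arithmetic would.
#'
#' @param x Numeric amount in euros.
#' @return Numeric rounded to 2 decimals.
#' @export
round_currency <- function(x) round(eur_to_me(x) / 10) / 100

# Evaluate `code` under a locally-seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
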
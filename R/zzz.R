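#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} after \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards; with \code{seed = NULL} the code runs on the
#' current stream.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.onLoad <- function(libname, pkgname) {
  register_routine("rtimes", rtimes)
  register_routine("scacum", scacum)
  register_routine("amod", amod)
  register_routine("moveYr", move_yr)
  register_routine("move_yr", move_yr)
  register_routine("wlai", wlai_group)
  invisible()
}
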
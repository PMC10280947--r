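#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions can be deterministic without clobbering
#' the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Shared categorical level sets for the patient-record schema.
site_levels <- function() {
  c("bladder", "breast", "gastrointestinal", "gynecological", "head&neck",
    "kidney", "lung", "melanoma/skin", "pancreas", "prostate",
    "soft tissue&bones", "other")
}

gender_levels <- function() c("female", "male")

outcome_levels <- function() c("one", "more")

`%||%` <- function(a, b) if (is.null(a)) b else a
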
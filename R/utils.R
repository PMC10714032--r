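# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so every stochastic operation in the package is a pure
#' function of its arguments and seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
check_groups <- function(groups, samples) {
  if (is.null(names(groups))) names(groups) <- samples
  groups <- groups[samples]
  if (anyNA(groups)) stop2("every sample needs a group assignment")
  lv <- unique(groups)
  if (length(lv) != 2L) {
    stop2("groups must partition the samples into exactly two non-empty sets")
  }
  groups
}

# The two group labels in a stable order: 'control' first if present,
# otherwise alphabetical.
#' @noRd
group_levels <- function(groups) {
  lv <- unique(as.character(groups))
  if ("control" %in% lv) c("control", setdiff(lv, "control")) else sort(lv)
}
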
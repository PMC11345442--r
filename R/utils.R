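#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test coef complete.cases ks.test mad median
#'   p.adjust pchisq pnorm quantile rbinom rexp rlnorm rnorm rpois runif
#'   sd setNames var wilcox.test rbeta
#' @importFrom utils head read.delim write.table packageVersion tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic stage of the package draws from its own RNG stream,
#' seeded by a deterministic hash of the master seed and a fixed label.
#' Adding a new stage therefore never perturbs the draws of another.
#'
#' @param seed master seed (integer).
#' @param label character stage label, e.g. `"genome"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h * 97 + 17) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
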
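#' @importFrom stats rnorm runif sd quantile plogis setNames median
#' @importFrom stats phyper p.adjust dist hclust
#' @importFrom utils head write.csv read.csv write.table read.delim
"_PACKAGE"

#' Derive a stream-specific seed from a root seed
#'
#' All randomness in dvpflow flows from a single integer root seed. Each
#' consumer (nuclei generator, protein-matrix generator, imputation,
#' permutation engine, ...) derives its own sub-seed with a labelled
#' multiplicative hash so that stages are statistically decoupled while the
#' whole pipeline stays reproducible from one number.
#'
#' @param seed integer root seed.
#' @param label character stream label, e.g. `"nuclei"` or `"impute"`.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "nuclei")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)
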
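#' @importFrom stats median rbinom rpois runif setNames kruskal.test pnorm quantile
#' @importFrom utils head tail
NULL

# Raw byte codes for the 5-letter consensus alphabet.
.BASES <- c("A", "C", "G", "T")
.RAW_BASES <- charToRaw("ACGT")
.RAW_N <- charToRaw("N")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' simulator calls do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Round half away from zero at a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), 0.5 always rounds up, matching
#' how percentages are conventionally printed in the field.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(6.25, 1)  # 6.3, where round() gives 6.2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Convert a sequence string to a raw vector and back.
seq_to_raw <- function(s) charToRaw(s)
raw_to_seq <- function(r) rawToChar(r)

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
}
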
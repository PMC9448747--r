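`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to compare recovered cluster labels against generator truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  abort_if(length(a) != length(b), "label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Benjamini-Hochberg wrapper kept explicit so callers read as intended.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Deterministic RNG scope: every stochastic operation takes a seed and runs
# inside with_seed so global RNG state is never consumed or disturbed.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
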
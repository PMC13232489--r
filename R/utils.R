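# Small shared helpers: DNA string ops on plain characters, rounding, RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors (alphabet
#' ACGTN).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complementBase <- function(b) chartr("ACGTN", "TGCAN", b)

#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), exact halves are rounded away
#' from zero, matching how the survey percentages are printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

gcPercent <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

randomDNA <- function(n, gc = 0.36) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Integer allocation of `total` across proportions, largest-remainder method;
# deterministic, sums exactly to total.
allocateCounts <- function(total, props) {
  props <- props / sum(props)
  raw <- props * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
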
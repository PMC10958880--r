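# Fisher's exact test for 2x2 contingency tables, implemented from the
# hypergeometric point probability
#
#   P(table) = (a+b)! (c+d)! (a+c)! (b+d)! / ( a! b! c! d! n! )
#
# evaluated in log-factorial arithmetic (no normal approximation). The test
# p-value sums the point probabilities of all tables sharing the observed
# margins that are as or more extreme under the chosen alternative; the
# point probability and the tail sum are distinct quantities and both are
# exposed.

#' Point probability of a 2x2 table
#'
#' @param a,b,c,d Non-negative integer counts laid out as
#'   hit/not-hit x in-cluster/not-in-cluster.
#' @return The exact hypergeometric probability of the table given its
#'   margins.
#' @export
fisher_point_probability <- function(a, b, c, d) {
  check_table(a, b, c, d)
  n <- a + b + c + d
  exp(lgamma(a + b + 1) + lgamma(c + d + 1) + lgamma(a + c + 1) +
        lgamma(b + d + 1) -
        (lgamma(a + 1) + lgamma(b + 1) + lgamma(c + 1) + lgamma(d + 1) +
           lgamma(n + 1)))
}

#' Fisher's exact test p-value
#'
#' Exact tail sum over all tables with the observed margins. With
#' `alternative = "greater"` (the default throughout the enrichment module:
#' the question is whether hits are over-represented in a cluster) the tail
#' is all tables with `a` at least as large as observed; `"two_sided"` sums
#' every table whose point probability does not exceed the observed one
#' (within a 1 + 1e-7 relative tolerance, the usual convention).
#'
#' Degenerate margins (an all-zero row or column) give p = 1.
#'
#' @param a,b,c,d Table counts; alternatively `a` may be a length-4 vector
#'   or 2x2 matrix.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact(3, 1, 1, 3, alternative = "greater")
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (is.null(b)) {
    v <- as.integer(a)
    stopifnot(length(v) == 4)
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  }
  check_table(a, b, c, d)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  amin <- max(0, r1 + c1 - n)
  amax <- min(r1, c1)
  avals <- amin:amax
  logp <- lgamma(r1 + 1) + lgamma(n - r1 + 1) + lgamma(c1 + 1) +
    lgamma(n - c1 + 1) - lgamma(n + 1) -
    (lgamma(avals + 1) + lgamma(r1 - avals + 1) + lgamma(c1 - avals + 1) +
       lgamma(n - r1 - c1 + avals + 1))
  probs <- exp(logp)
  obs <- probs[avals == a]
  p <- switch(alternative,
    greater = sum(probs[avals >= a]),
    two_sided = sum(probs[probs <= obs * (1 + 1e-7)])
  )
  min(1, p)
}

check_table <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
    abort("contingency counts must be non-negative integers")
  }
  invisible(TRUE)
}
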
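#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pnorm qnorm pchisq dnorm integrate uniroot optimise
#'   rnorm rbinom runif median mad sd cor lm coef density weighted.mean
#'   complete.cases setNames optim ks.test approx
NULL

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic per-component seed stream. A master seed expands to
# component streams as (master * 48271 + index * 9973) mod (2^31 - 1),
# with a fixed component -> index table, so that changing one component's
# draws never perturbs another's.
stream_seed <- function(master_seed, component) {
  idx <- switch(component,
    panel = 1L, exposure = 2L, metabolite = 3L, outcome = 4L,
    palindrome = 5L, coloc = 6L, bootstrap = 7L, replication = 8L,
    abort(paste0("unknown seed component '", component, "'"))
  )
  s <- (as.numeric(master_seed) %% 2147483647) * 48271 + idx * 9973
  as.integer(s %% 2147483647) + 1L
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))

ci_from <- function(beta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

assert_count <- function(x, name) {
  if (!is_count(x)) abort(paste0("`", name, "` must be a positive integer count"))
  invisible(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- length(x) == 1 && is.numeric(x) && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) abort(paste0("`", name, "` must lie in ", if (open_lo) "(" else "[",
                        lo, ", ", hi, if (open_hi) ")" else "]"))
  invisible(x)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

flip_allele <- function(a) unname(COMPLEMENT[a])

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
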
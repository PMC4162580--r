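#' Discretize an expression matrix to ternary categories
#'
#' Each gene is standardized to mean 0 and sample standard deviation 1
#' (n - 1 denominator) and mapped to three categories: standardized value
#' < -1 -> 0 (low), in \[-1, 1\] -> 1 (mid, boundaries inclusive), > 1 -> 2
#' (high). Constant genes map entirely to the mid category. The G2 test
#' operates on this representation.
#'
#' @param expr numeric genes x samples matrix (>= 2 samples).
#' @return Integer matrix of the same shape and dimnames with values in
#'   {0, 1, 2}.
#' @examples
#' m <- rbind(a = c(-3, -1, 1, 3), b = rep(2, 4))
#' discretize_ternary(m)
#' @export
discretize_ternary <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  z <- t(scale(t(expr)))          # per-gene standardization, sd with n-1
  z[!is.finite(z)] <- 0           # constant genes -> mid category
  out <- matrix(1L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  out[z < -1] <- 0L
  out[z > 1] <- 2L
  out
}

ci_test_result <- function(statistic, p_value, n, cond_size, reliable) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 cond_size = cond_size, reliable = reliable),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("CI test: statistic = %.4g, p = %.4g, n = %d, |S| = %d%s\n",
              x$statistic, x$p_value, x$n, x$cond_size,
              if (x$reliable) "" else " (unreliable)"))
  invisible(x)
}

#' Fisher's Z conditional-independence test
#'
#' Tests independence of genes `i` and `j` given a conditioning set via the
#' partial correlation r obtained by inverting the sample correlation matrix
#' of `{i, j}` and the conditioning genes. The statistic is
#' `sqrt(n - |S| - 3) * |atanh(r)|`, compared against the standard normal
#' tail (two-sided). r is clamped to `1 - 1e-7` in absolute value before the
#' transform so perfectly correlated replicate pairs yield a finite
#' statistic. A singular correlation submatrix (e.g. a constant gene) gives
#' `reliable = FALSE` and p = 1.
#'
#' @param expr numeric genes x samples matrix with rownames.
#' @param i,j gene identifiers (or row indices), `i != j`, neither in `cond`.
#' @param cond character vector of conditioning gene identifiers (possibly
#'   empty). Requires `ncol(expr) > length(cond) + 3`.
#' @return A `ci_test_result`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 3, 100, dimnames = list(c("a", "b", "c"), NULL))
#' fisher_z_test(x, "a", "b", cond = "c")
#' @export
fisher_z_test <- function(expr, i, j, cond = character()) {
  vars <- resolve_genes(expr, i, j, cond)
  n <- ncol(expr)
  k <- length(vars$cond)
  if (n <= k + 3) stop("need more than |cond| + 3 samples for Fisher's Z")
  r <- tryCatch(
    partial_cor(expr[c(vars$i, vars$j, vars$cond), , drop = FALSE]),
    error = function(e) NA_real_)
  if (!is.finite(r)) {
    return(ci_test_result(0, 1, n, k, reliable = FALSE))
  }
  r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
  z <- atanh(r)
  stat <- sqrt(n - k - 3) * abs(z)
  ci_test_result(stat, 2 * pnorm(-stat), n, k, reliable = TRUE)
}

# Partial correlation of rows 1 and 2 of `x` given the remaining rows,
# via inversion of the sample correlation matrix.
partial_cor <- function(x) {
  R <- suppressWarnings(cor(t(x)))   # zero-variance genes give NA, handled below
  if (anyNA(R)) stop("undefined correlation (constant gene)")
  if (nrow(R) == 2L) return(R[1, 2])
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

resolve_genes <- function(mat, i, j, cond) {
  ids <- rownames(mat)
  as_id <- function(g) {
    if (is.numeric(g)) ids[g] else as.character(g)
  }
  i <- as_id(i); j <- as_id(j); cond <- vapply(cond, as_id, character(1))
  cond <- unname(cond)
  if (!all(c(i, j, cond) %in% ids)) stop("unknown gene identifier")
  if (i == j) stop("i and j must differ")
  if (i %in% cond || j %in% cond) stop("i and j must not be in `cond`")
  list(i = i, j = j, cond = cond)
}

#' G2 conditional-independence test on ternary data
#'
#' Likelihood-ratio test of independence between two ternary-discretized
#' genes within each joint stratum of the conditioning genes:
#' `G2 = 2 * sum O * log(O / E)` summed over the 3 x 3 table of every
#' non-empty stratum, with expected counts from the row/column margins
#' within the stratum and zero observed counts contributing nothing.
#' Degrees of freedom are fixed at `4 * (number of non-empty strata)`. The
#' test is flagged unreliable when `n < 5 * 9 * (number of non-empty
#' strata)` (fewer than five samples per table cell on average) or when
#' either tested gene falls entirely in one category; unreliable tests must
#' not be used to remove edges.
#'
#' @param tern integer genes x samples matrix in {0, 1, 2}, e.g. from
#'   [discretize_ternary()].
#' @inheritParams fisher_z_test
#' @return A `ci_test_result`.
#' @examples
#' z <- rbind(x = rep(0:2, each = 10), y = rep(0:2, each = 10))
#' g2_test(z, "x", "y")
#' @export
g2_test <- function(tern, i, j, cond = character()) {
  vars <- resolve_genes(tern, i, j, cond)
  n <- ncol(tern)
  k <- length(vars$cond)
  xi <- tern[vars$i, ]
  xj <- tern[vars$j, ]
  if (length(unique(xi)) < 2L || length(unique(xj)) < 2L) {
    return(ci_test_result(0, 1, n, k, reliable = FALSE))
  }
  # integer-coded contingency tabulation: stratum code from the joint
  # conditioning configuration, cell code from (xi, xj) within stratum
  scode <- rep(0L, n)
  if (k > 0L) {
    for (t in seq_len(k)) {
      scode <- scode * 3L + as.integer(tern[vars$cond[t], ])
    }
  }
  scode <- match(scode, sort(unique(scode))) - 1L   # compact stratum index
  n_strata_total <- max(scode) + 1L
  counts <- tabulate(scode * 9L + as.integer(xi) * 3L + as.integer(xj) + 1L,
                     nbins = 9L * n_strata_total)
  O <- array(counts, dim = c(3L, 3L, n_strata_total))  # [xj, xi, stratum]
  g2 <- 0
  n_strata <- 0L
  for (s in seq_len(n_strata_total)) {
    Os <- O[, , s]
    ns <- sum(Os)
    if (ns == 0L) next
    n_strata <- n_strata + 1L
    E <- outer(rowSums(Os), colSums(Os)) / ns
    nz <- Os > 0
    g2 <- g2 + 2 * sum(Os[nz] * log(Os[nz] / E[nz]))
  }
  g2 <- max(g2, 0)
  df <- 4L * n_strata
  reliable <- n >= 5L * 9L * n_strata
  ci_test_result(g2, pchisq(g2, df, lower.tail = FALSE), n, k, reliable)
}
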
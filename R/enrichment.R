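logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric tail probability for set over/under-representation
#'
#' For a population of `N` genes of which `K` carry the property, and a
#' sample (e.g. the up-regulated genes) of size `n` containing `k`
#' carriers: `direction = "over"` gives `P(X >= k)` and `"under"` gives
#' `P(X <= k)` (both inclusive of `k`). Tail sums are accumulated in log
#' space with log-gamma terms, so probabilities far below double underflow
#' of individual factorials (e.g. 1e-80) remain accurate, and `log10_p` is
#' returned alongside `p`.
#'
#' @param N Population size.
#' @param K Population successes (carriers).
#' @param n Sample size.
#' @param k Sample successes.
#' @param direction `"over"` or `"under"`.
#' @return One-row tibble `N, K, n, k, direction, p, log10_p, fold` where
#'   `fold = (k/n) / (K/N)`.
#' @export
#' @examples
#' hypergeom_tail(10, 4, 5, 3, "over")  # 66/252
hypergeom_tail <- function(N, K, n, k, direction = c("over", "under")) {
  direction <- match.arg(direction)
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); k <- as.integer(k)
  if (anyNA(c(N, K, n, k)) || N < 0 || K < 0 || n < 0 || k < 0)
    stop("counts must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > n) stop("impossible counts: k > n")
  if (k > K) stop("impossible counts: k > K")
  if (k < max(0L, n + K - N)) stop("impossible counts: k < max(0, n + K - N)")
  ldh <- function(x) lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  xs <- if (direction == "over") seq(k, min(n, K)) else seq(max(0L, n + K - N), k)
  lp <- logsumexp(ldh(xs))
  lp <- min(lp, 0)  # guard tiny positive rounding
  tibble::tibble(
    N = N, K = K, n = n, k = k, direction = direction,
    p = exp(lp), log10_p = lp / log(10),
    fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  )
}

#' Mann-Whitney U test (midrank ties)
#'
#' `U` is the statistic of the first sample. For pooled sizes up to
#' `exact_max` the two-sided P-value is computed by exhaustive enumeration
#' of all group-label assignments of the pooled (possibly tied) values:
#' `P(|U' - mu| >= |U - mu|)` with `mu = n_a * n_b / 2`. Above that, a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest pooled size for exact enumeration.
#' @return One-row tibble `U, p_value, method`.
#' @export
#' @examples
#' mann_whitney_u(1:3, 4:6)  # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b, exact_max = 20L) {
  if (length(a) == 0 || length(b) == 0) stop("empty input sample")
  stopifnot(is.numeric(a), is.numeric(b), !anyNA(a), !anyNA(b))
  na <- length(a); nb <- length(b); nn <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)   # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (nn <= exact_max) {
    combos <- utils::combn(nn, na)
    rs <- colSums(matrix(r[combos], nrow = na))
    Us <- rs - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- na * nb / 12 * ((nn + 1) - tiecor)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(U = U, p_value = p, method = method)
}

#' Hypergeometric enrichment of ITR genes among a DE call
#'
#' Tests whether genes carrying an ITR are over- or under-represented in
#' the subset of genes with a given differential-expression call. The
#' population is the full record set (typically genes with detectable
#' expression), `K` the ITR carriers, `n` the genes with the call and `k`
#' their intersection; delegates to [hypergeom_tail()] so all four counts
#' are auditable in the result.
#'
#' @param records Output of [gene_integration()].
#' @param condition Which call column to test: `"call_a"` or `"call_b"`.
#' @param call The DE call defining the sample (`"up"` or `"down"`).
#' @param direction Tail direction (`"over"` or `"under"`).
#' @return One-row tibble as from [hypergeom_tail()], plus `condition` and
#'   `call` columns.
#' @export
itr_gene_enrichment <- function(records, condition = c("call_a", "call_b"),
                                call = c("up", "down"),
                                direction = c("over", "under")) {
  condition <- match.arg(condition)
  call <- match.arg(call)
  direction <- match.arg(direction)
  N <- nrow(records)
  K <- sum(records$has_itr)
  sel <- records[[condition]] == call
  n <- sum(sel)
  k <- sum(sel & records$has_itr)
  if (K == 0 || n == 0) {
    res <- tibble::tibble(N = N, K = K, n = n, k = k,
                          direction = direction, p = 1, log10_p = 0,
                          fold = NA_real_)
  } else {
    res <- hypergeom_tail(N, K, n, k, direction)
  }
  dplyr::mutate(res, condition = condition, call = call)
}
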
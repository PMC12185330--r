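## Correlations between genetic scores: maximum-likelihood tetrachoric
## correlation for dichotomized pairs, product-moment for continuous pairs.

#' Two-by-two contingency table
#'
#' Cell counts for a pair of dichotomized variables: `n11` both positive,
#' `n10` first positive only, `n01` second positive only, `n00` neither.
#'
#' @param n11,n10,n01,n00 Non-negative counts.
#' @return A `two_by_two` list.
#' @export
two_by_two <- function(n11, n10, n01, n00) {
  counts <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(as.list(counts), class = "two_by_two")
}

## Upper-right bivariate standard normal rectangle P(X > h, Y > k; rho),
## reduced to one-dimensional quadrature over x:
##   integral_h^Inf dnorm(x) * pnorm((rho * x - k) / sqrt(1 - rho^2)) dx
.binorm_upper <- function(h, k, rho) {
  if (rho >= 1) return(1 - pnorm(max(h, k)))
  if (rho <= -1) return(max(0, (1 - pnorm(h)) - pnorm(k)))
  if (abs(rho) < 1e-12) return((1 - pnorm(h)) * (1 - pnorm(k)))
  s <- sqrt(1 - rho^2)
  val <- integrate(function(x) dnorm(x) * pnorm((rho * x - k) / s),
                   lower = h, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
  min(max(val, 0), 1)
}

## Log-likelihood of a 2x2 table under the bivariate-normal threshold model
## with thresholds fixed at the observed margins.
.tetra_loglik <- function(rho, counts, h, k, pA, pB) {
  p11 <- .binorm_upper(h, k, rho)
  eps <- 1e-12
  p10 <- max(pA - p11, eps)
  p01 <- max(pB - p11, eps)
  p00 <- max(1 - pA - pB + p11, eps)
  p11 <- max(p11, eps)
  counts["n11"] * log(p11) + counts["n10"] * log(p10) +
    counts["n01"] * log(p01) + counts["n00"] * log(p00)
}

#' Maximum-likelihood tetrachoric correlation
#'
#' Thresholds are set from the margins (`h = qnorm(1 - P(row positive))`,
#' `k = qnorm(1 - P(col positive))`) and the latent correlation maximizes
#' the bivariate-normal cell-probability likelihood by bounded scalar
#' optimization; the standard error comes from the observed information
#' (numerical second derivative at the maximum).
#'
#' @param table A [two_by_two()].
#' @param correct Add a 0.5 continuity correction to every cell (off by
#'   default); required when a cell is zero but margins are positive.
#' @return A `correlation_estimate`: list(rho, se, method, n).
#' @export
tetrachoric_mle <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  counts <- unlist(table)
  if (correct) counts <- counts + 0.5
  n <- sum(counts)
  margins <- c(counts["n11"] + counts["n10"],  # row positive
               counts["n01"] + counts["n00"],
               counts["n11"] + counts["n01"],  # col positive
               counts["n10"] + counts["n00"])
  if (any(margins == 0))
    stop("zero margin in 2x2 table; consider the continuity correction ",
         "(correct = TRUE, +0.5 per cell)")
  pA <- (counts["n11"] + counts["n10"]) / n
  pB <- (counts["n11"] + counts["n01"]) / n
  h <- qnorm(1 - pA)
  k <- qnorm(1 - pB)
  eps <- 1e-6
  opt <- optimize(function(r) .tetra_loglik(r, counts, h, k, pA, pB),
                  interval = c(-1 + eps, 1 - eps), maximum = TRUE,
                  tol = 1e-9)
  rho <- opt$maximum
  dl <- 1e-4
  ll <- function(r) .tetra_loglik(r, counts, h, k, pA, pB)
  info <- -(ll(min(rho + dl, 1 - eps)) - 2 * ll(rho) +
              ll(max(rho - dl, -1 + eps))) / dl^2
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  structure(list(rho = unname(rho), se = unname(se),
                 method = "tetrachoric", n = unname(n)),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat("<correlation_estimate> ", x$method, ": rho = ",
      format(round(x$rho, 4)), " (SE ", format(round(x$se, 4)), "), n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Correlation between two genetic score vectors
#'
#' Product-moment correlation of the continuous z-scores, or tetrachoric
#' correlation after a median split of each score (the dichotomization used
#' when a latent-scale correlation between scores is wanted).
#'
#' @param scores_a,scores_b Numeric vectors (paired, same subjects and
#'   order) or `genetic_scores` tables sharing ids.
#' @param method `"product-moment"` (default) or `"tetrachoric"`.
#' @return A `correlation_estimate`.
#' @export
score_correlation <- function(scores_a, scores_b,
                              method = c("product-moment", "tetrachoric")) {
  method <- match.arg(method)
  if (is.data.frame(scores_a) && all(c("id", "z") %in% names(scores_a))) {
    m <- merge(as.data.table(scores_a)[, .(id, za = z)],
               as.data.table(scores_b)[, .(id, zb = z)], by = "id")
    a <- m$za; b <- m$zb
  } else {
    a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  }
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("fewer than 3 complete score pairs")
  if (method == "product-moment") {
    r <- cor(a, b)
    se <- (1 - r^2) / sqrt(n - 1)
    structure(list(rho = r, se = se, method = "product-moment", n = n),
              class = "correlation_estimate")
  } else {
    ap <- a > median(a)
    bp <- b > median(b)
    tab <- two_by_two(sum(ap & bp), sum(ap & !bp), sum(!ap & bp),
                      sum(!ap & !bp))
    tetrachoric_mle(tab)
  }
}
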
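#' Spearman rank correlation with a large-sample p-value
#'
#' Ranks (average ranks for ties) are correlated with Pearson's formula;
#' the p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' on `n - 2` degrees of freedom. For `n <= 10` an exact permutation
#' p-value can be requested instead.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, finite.
#' @param exact Use the exact permutation null (only for `n <= 10`).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact && n <= 10L) {
    perms <- perm_all(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], n, after = pos - 1L)
  }
  out
}

#' Pairwise inter-rater Spearman matrix
#'
#' @param m Numeric matrix, participants x raters, of combined
#'   per-participant scores; `NA` allowed (pairwise complete).
#' @return Symmetric rater x rater matrix with unit diagonal; cells
#'   with fewer than 3 shared participants are `NA`.
#' @export
pairwise_rater_matrix <- function(m) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 raters", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- paste0("rater", seq_len(k))
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    out[i, j] <- out[j, i] <- if (sum(ok) < 3L) NA_real_ else
      spearman_rho(m[ok, i], m[ok, j])$rho
  }
  out
}

#' Two-way agreement intraclass correlation, single measure
#'
#' ICC(A,1): two-way random effects, absolute agreement, single
#' measurement, computed from the standard two-way mean squares of the
#' participants x raters table:
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' Absolute agreement penalizes systematic rater offsets, unlike the
#' consistency variant. `type = "A,k"` gives the average-measures form.
#'
#' @param m Complete numeric matrix, participants (n >= 3) x raters
#'   (k >= 2).
#' @param type `"A,1"` (default) or `"A,k"`.
#' @return List with `icc`, `ms` (MSR, MSC, MSE), `n`, `k`, and
#'   `degenerate` (TRUE when between-participant variance is zero).
#' @export
icc_two_way_agreement <- function(m, type = c("A,1", "A,k")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (anyNA(m)) stop("ICC requires a complete matrix", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L)
    stop("ICC needs >= 3 participants and >= 2 raters", call. = FALSE)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (type == "A,1")
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (msc - mse) / n)
  degenerate <- msr <= .Machine$double.eps
  if (degenerate)
    warning("zero between-participant variance; ICC is degenerate")
  list(icc = icc, ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k,
       degenerate = degenerate)
}

#' Flag participants whose two raters disagree beyond a threshold
#'
#' Participants with an absolute score discrepancy strictly greater
#' than `threshold` (default 1.0) are flagged for consensus discussion;
#' a discrepancy of exactly the threshold is not flagged.
#'
#' @param scores_a,scores_b Named or aligned numeric score vectors from
#'   the two raters.
#' @param threshold Strict discrepancy cut, default 1.0.
#' @param ids Optional participant identifiers (defaults to names of
#'   `scores_a` or the index).
#' @return Data frame of flagged participants with both scores and the
#'   discrepancy; zero rows when none.
#' @export
consensus_flags <- function(scores_a, scores_b, threshold = 1.0,
                            ids = NULL) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors are not aligned (lengths ", length(scores_a),
         " vs ", length(scores_b), ")", call. = FALSE)
  if (is.null(ids))
    ids <- names(scores_a) %||% seq_along(scores_a)
  disc <- abs(scores_a - scores_b)
  sel <- which(disc > threshold)
  data.frame(subject_id = ids[sel], score_a = unname(scores_a[sel]),
             score_b = unname(scores_b[sel]),
             discrepancy = unname(disc[sel]), stringsAsFactors = FALSE)
}
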
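check_rankings <- function(r1, r2) {
  if (length(r1) < 2L || length(r2) < 2L) {
    stop_rnac("ranking_error", "rankings need at least two items")
  }
  if (length(r1) != length(r2) || anyDuplicated(r1) || anyDuplicated(r2) ||
      !setequal(r1, r2)) {
    stop_rnac("ranking_error",
              "rankings must be permutations of the same item set")
  }
}

#' Spearman's rank correlation between two rankings
#'
#' For tie-free rankings of `k` items: `1 - 6 * sum(d^2) / (k (k^2 - 1))`,
#' where `d` is the per-item rank difference.
#'
#' @param r1,r2 Rankings: vectors of the same items in ranked order.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(c("a", "b", "c"), c("b", "a", "c"))
spearman_rho <- function(r1, r2) {
  check_rankings(r1, r2)
  k <- length(r1)
  d <- match(r1, r2) - seq_len(k)
  1 - 6 * sum(d^2) / (k * (k^2 - 1))
}

#' Kendall's tau between two rankings
#'
#' `(concordant - discordant) / (k (k - 1) / 2)` over all item pairs.
#'
#' @inheritParams spearman_rho
#' @return Correlation in `[-1, 1]`.
#' @export
kendall_tau <- function(r1, r2) {
  check_rankings(r1, r2)
  k <- length(r1)
  p2 <- match(r1, r2)  # rank in r2 of the item at each r1 position
  conc <- 0L
  for (a in seq_len(k - 1L)) {
    conc <- conc + sum(p2[(a + 1L):k] > p2[a])
  }
  m <- k * (k - 1L) / 2
  (2 * conc - m) / m
}

#' Top-fraction enrichment score
#'
#' Overlap of the top `k = max(1, floor(f * n))` items of both rankings,
#' normalized by `f^2 * n` (so a random pair has expectation about 1).  With
#' 13 items and `f = 0.25` the top three positions are compared.
#'
#' @inheritParams spearman_rho
#' @param top_fraction Fraction `f` of the list treated as "top", in (0, 1].
#' @return Non-negative enrichment value.
#' @export
enrichment_score <- function(r1, r2, top_fraction = 0.25) {
  check_rankings(r1, r2)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop_rnac("parameter_error", "top_fraction must lie in (0, 1]")
  }
  n <- length(r1)
  k <- max(1L, floor(top_fraction * n))
  length(intersect(r1[seq_len(k)], r2[seq_len(k)])) / (top_fraction^2 * n)
}

#' Rank-biased overlap (extrapolated)
#'
#' `RBO = (1 - p) * sum_{d=1}^{k} p^(d-1) * A_d + p^k * A_k`, where `A_d` is
#' the overlap of the depth-`d` prefixes divided by `d` and `p` is the
#' persistence (weight decay) parameter.  Higher `p` looks deeper down the
#' rankings; `p = 0` compares only the top item.
#'
#' @inheritParams spearman_rho
#' @param p Persistence in `[0, 1)`.
#' @return Overlap in `[0, 1]`.
#' @export
rank_biased_overlap <- function(r1, r2, p = 0.9) {
  check_rankings(r1, r2)
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1) {
    stop_rnac("parameter_error", "persistence p must lie in [0, 1)")
  }
  k <- length(r1)
  a <- vapply(seq_len(k), function(d)
    length(intersect(r1[seq_len(d)], r2[seq_len(d)])) / d, 0)
  (1 - p) * sum(p^(seq_len(k) - 1L) * a) + p^k * a[k]
}

# ---- vectorized engine over rank matrices ------------------------------

# n x k matrix of uniform random permutation ranks: row i gives the rank of
# each of the k items in ranking i
random_rank_matrix <- function(n, k) {
  u <- matrix(stats::runif(n * k), n, k)
  ord <- order(row(u), u)               # linear indices sorted within rows
  item <- ((ord - 1L) %/% n) + 1L       # item (column) at each sorted slot
  r <- matrix(0L, n, k)
  r[cbind(rep(seq_len(n), each = k), item)] <- rep.int(seq_len(k), n)
  r
}

# per-row metrics for paired rank matrices R1, R2 (n x k)
rowwise_metrics <- function(r1m, r2m, metrics, es_fraction, rbo_p) {
  n <- nrow(r1m); k <- ncol(r1m)
  out <- list()
  if ("rho" %in% metrics) {
    out$rho <- 1 - 6 * rowSums((r1m - r2m)^2) / (k * (k^2 - 1))
  }
  if ("tau" %in% metrics) {
    conc <- numeric(n)
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      conc <- conc + ((r1m[, a] > r1m[, b]) == (r2m[, a] > r2m[, b]))
    }
    m <- k * (k - 1L) / 2
    out$tau <- (2 * conc - m) / m
  }
  if ("es" %in% metrics) {
    kk <- max(1L, floor(es_fraction * k))
    out$es <- rowSums((r1m <= kk) & (r2m <= kk)) / (es_fraction^2 * k)
  }
  if ("rbo" %in% metrics) {
    acc <- numeric(n)
    a_d <- numeric(n)
    for (d in seq_len(k)) {
      a_d <- rowSums((r1m <= d) & (r2m <= d)) / d
      acc <- acc + (1 - rbo_p) * rbo_p^(d - 1L) * a_d
    }
    out$rbo <- acc + rbo_p^k * a_d
  }
  out
}

#' Null model of random ranking pairs
#'
#' Monte-Carlo baseline for a "random ranker": batches of independent
#' uniform random permutation pairs are drawn, each batch's mean of every
#' ranking-similarity metric is recorded, and the empirical 2.5/97.5
#' percentiles of the batch means give the 95% confidence interval.  For
#' Spearman's rho the half-width is analytically about
#' `1.96 / (sqrt(n_items - 1) * sqrt(pairs_per_batch))`.
#'
#' @param n_items Number of ranked items (>= 2).
#' @param pairs_per_batch Random ranking pairs per batch.
#' @param n_batches Number of batches.
#' @param seed Optional integer seed for reproducibility.
#' @param metrics Subset of `c("rho", "tau", "es", "rbo")`.
#' @param es_fraction Top fraction for the enrichment score.
#' @param rbo_p RBO persistence.
#' @return A `null_model_ci`: list with `params`, `ci` (data frame `metric,
#'   lower, upper, mean, sd`), and `batch_means` (matrix `n_batches` x
#'   metrics, the null sampling distribution).
#' @export
#' @examples
#' null_model_ci(13, 100, 200, seed = 1)$ci
null_model_ci <- function(n_items, pairs_per_batch, n_batches, seed = NULL,
                          metrics = c("rho", "tau", "es", "rbo"),
                          es_fraction = 0.25, rbo_p = 0.9) {
  if (n_items < 2L) stop_rnac("parameter_error", "n_items must be >= 2")
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  bm <- matrix(NA_real_, n_batches, length(metrics),
               dimnames = list(NULL, metrics))
  chunk <- max(1L, min(n_batches, floor(250000 / pairs_per_batch)))
  done <- 0L
  while (done < n_batches) {
    nb <- min(chunk, n_batches - done)
    n <- nb * pairs_per_batch
    r1m <- random_rank_matrix(n, n_items)
    r2m <- random_rank_matrix(n, n_items)
    vals <- rowwise_metrics(r1m, r2m, metrics, es_fraction, rbo_p)
    grp <- rep(seq_len(nb), each = pairs_per_batch)
    for (mname in metrics) {
      bm[done + seq_len(nb), mname] <-
        as.vector(rowsum(vals[[mname]], grp)) / pairs_per_batch
    }
    done <- done + nb
  }
  ci <- data.frame(
    metric = metrics,
    lower = apply(bm, 2L, stats::quantile, 0.025, names = FALSE),
    upper = apply(bm, 2L, stats::quantile, 0.975, names = FALSE),
    mean = colMeans(bm),
    sd = apply(bm, 2L, stats::sd),
    stringsAsFactors = FALSE)
  rownames(ci) <- NULL
  out <- list(params = list(n_items = n_items,
                            pairs_per_batch = pairs_per_batch,
                            n_batches = n_batches, seed = seed,
                            es_fraction = es_fraction, rbo_p = rbo_p),
              ci = ci, batch_means = bm)
  class(out) <- "null_model_ci"
  out
}

#' @export
print.null_model_ci <- function(x, ...) {
  p <- x$params
  cat(sprintf("<null_model_ci> %d items, %d pairs x %d batches\n",
              p$n_items, p$pairs_per_batch, p$n_batches))
  print.data.frame(x$ci, digits = 4)
  invisible(x)
}

#' Cohen's d effect size against a null distribution
#'
#' `d = (mean(sample) - null_mean) / null_sd`.  Magnitudes above 0.8 count
#' as a very strong effect.
#'
#' @param sample_means Numeric sample (e.g. per-run similarity values).
#' @param null_mean,null_sd Mean and standard deviation of the null
#'   distribution (`null_sd > 0`).
#' @return List with `d` and a qualitative `label`.
#' @export
effect_size <- function(sample_means, null_mean, null_sd) {
  if (!is.numeric(null_sd) || length(null_sd) != 1L || null_sd <= 0) {
    stop_rnac("undefined_effect", "null_sd must be a positive number")
  }
  d <- (mean(sample_means) - null_mean) / null_sd
  label <- if (abs(d) > 0.8) "very strong"
           else if (abs(d) >= 0.5) "medium"
           else if (abs(d) >= 0.2) "small"
           else "negligible"
  list(d = d, label = label)
}

#' Welch tests with Benjamini-Hochberg correction across noise levels
#'
#' For each level's sample, a two-sided Welch t-test (Welch-Satterthwaite
#' degrees of freedom) against the null sample; the p-values are then
#' adjusted by the Benjamini-Hochberg step-up procedure across all levels.
#'
#' @param level_samples Named list of numeric vectors (one per level, >= 2
#'   observations each).
#' @param null_samples Numeric vector of null observations (>= 2).
#' @return Data frame `level, t, df, p, p_adj`.
#' @export
significance_profile <- function(level_samples, null_samples) {
  stopifnot(is.list(level_samples), length(level_samples) >= 1L)
  if (length(null_samples) < 2L) {
    stop_rnac("parameter_error", "null sample needs >= 2 observations")
  }
  rows <- lapply(seq_along(level_samples), function(k) {
    x <- level_samples[[k]]
    if (length(x) < 2L) {
      stop_rnac("parameter_error", "level sample needs >= 2 observations")
    }
    if (stats::sd(x) == 0 && stats::sd(null_samples) == 0) {
      stop_rnac("degenerate_test",
                "zero variance in both groups at level %d", k)
    }
    tt <- stats::t.test(x, null_samples, var.equal = FALSE)
    data.frame(level = names(level_samples)[k] %||% as.character(k),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
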
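#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus one-way ANOVA on one variable across groups, followed by all
#' pairwise two-sample comparisons (Welch by default) with Bonferroni
#' correction: adjusted P = min(1, raw P x number of pairs). For five
#' groups the family is all 10 pairs.
#'
#' @param table data.frame with the variable and a group column.
#' @param variable name of the numeric column to test.
#' @param group name of the grouping column (default `"group_label"`).
#' @param pooled use pooled-variance t tests instead of Welch.
#' @return list of class `group_comparison`: `variable`, `F`, `p`,
#'   `df` (c(between, within)), and `pairwise` (data.frame with columns
#'   `group1`, `group2`, `mean_diff`, `p_raw`, `p_adj`).
#' @export
anova_bonferroni <- function(table, variable, group = "group_label",
                             pooled = FALSE) {
  stopifnot(variable %in% names(table), group %in% names(table))
  d <- data.frame(y = table[[variable]], g = factor(table[[group]]))
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$g)
  counts <- counts[counts > 0]
  if (length(counts) < 2L || any(counts < 2L))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  d$g <- droplevels(d$g)
  # classical sums of squares
  gm <- mean(d$y)
  means <- tapply(d$y, d$g, mean)
  ns <- tapply(d$y, d$g, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((d$y - means[d$g])^2)
  dfb <- length(means) - 1L
  dfw <- nrow(d) - length(means)
  if (ssw == 0) {
    if (ssb == 0) { Fstat <- 0; p <- 1 }
    else {
      warning("zero within-group variance: degenerate F (+Inf)", call. = FALSE)
      Fstat <- Inf; p <- 0
    }
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  lv <- levels(d$g)
  pairs <- utils::combn(lv, 2)
  npairs <- ncol(pairs)
  pw <- lapply(seq_len(npairs), function(i) {
    a <- d$y[d$g == pairs[1, i]]; b <- d$y[d$g == pairs[2, i]]
    pr <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = pooled)$p.value
    }
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               mean_diff = mean(a) - mean(b), p_raw = pr,
               p_adj = min(1, pr * npairs))
  })
  structure(list(variable = variable, F = Fstat, p = p,
                 df = c(between = dfb, within = dfw),
                 pairwise = do.call(rbind, pw)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%d, %d) = %.3f, P = %.4g\n",
              x$variable, x$df[1], x$df[2], x$F, x$p))
  print(transform(x$pairwise, p_raw = signif(p_raw, 3),
                  p_adj = signif(p_adj, 3)))
  invisible(x)
}

# Spearman rho with average ranks, plus two-sided P: t approximation for
# n > 10, Monte-Carlo permutation (seeded, 20000 draws) for small n.
spearman_one <- function(x, y, n_perm = 20000L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  if (n > 10L) {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  } else {
    rx <- rank(x); ry <- rank(y)
    null <- vapply(seq_len(n_perm), function(i)
      stats::cor(rx, sample(ry)), 0)
    p <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  c(rho = rho, p = p, n = n)
}

#' Spearman rank-correlation matrix with significance stars
#'
#' Rank correlation (average ranks for ties) between every coupling column
#' and every physiological column, with two-sided P values and the star
#' annotation thresholds 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param table data.frame of per-subject features.
#' @param coupling_cols,physio_cols character vectors of column names
#'   (rows and columns of the matrix).
#' @param n_perm Monte-Carlo permutations for small-sample (n <= 10) P
#'   values.
#' @param seed seed for the permutation draws.
#' @return list of class `spearman_matrix`: matrices `rho`, `p`, `stars`
#'   (character), `n`.
#' @export
spearman_matrix <- function(table, coupling_cols, physio_cols,
                            n_perm = 20000L, seed = 1L) {
  stopifnot(all(coupling_cols %in% names(table)),
            all(physio_cols %in% names(table)))
  set.seed(as.integer(seed))
  rho <- p <- nn <- matrix(NA_real_, length(coupling_cols),
                           length(physio_cols),
                           dimnames = list(coupling_cols, physio_cols))
  for (i in seq_along(coupling_cols))
    for (j in seq_along(physio_cols)) {
      r <- spearman_one(table[[coupling_cols[i]]], table[[physio_cols[j]]],
                        n_perm = n_perm)
      rho[i, j] <- r["rho"]; p[i, j] <- r["p"]; nn[i, j] <- r["n"]
    }
  stars <- matrix("", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  stars[!is.na(p) & p < 0.0001] <- "****"
  structure(list(rho = rho, p = p, stars = stars, n = nn),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("<spearman_matrix>", nrow(x$rho), "x", ncol(x$rho), "\n")
  m <- matrix(paste0(round(x$rho, digits), x$stars),
              nrow(x$rho), dimnames = dimnames(x$rho))
  print(m, quote = FALSE)
  invisible(x)
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param x a [spearman_matrix()].
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.spearman_matrix <- function(x, ...) {
  r <- x$rho
  nr <- nrow(r); nc <- ncol(r)
  graphics::image(seq_len(nc), seq_len(nr), t(r[nr:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = grDevices::hcl.colors(51, "Blue-Red 3"),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, seq_len(nc), colnames(r), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nr), rev(rownames(r)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Percent change between a reference and a comparison value
#'
#' `100 * (reference - comparison) / reference`: positive for a decline
#' from the reference, negative for a rise. Report text conventionally
#' rounds to one decimal.
#'
#' @param reference reference (e.g. lowland group mean); non-zero.
#' @param comparison comparison value (e.g. high-altitude group mean).
#' @return percent change (scalar, unrounded).
#' @export
#' @examples
#' percent_change(0.78, 0.66)   # 15.4% reduction
percent_change <- function(reference, comparison) {
  if (!is.finite(reference) || reference == 0)
    stop("reference must be non-zero", call. = FALSE)
  100 * (reference - comparison) / reference
}
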
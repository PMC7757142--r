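## Factorial (genotype x treatment) statistics: Type-III two-way ANOVA,
## Tukey-Kramer HSD over the four cells, Grubbs outlier test.

.check_factorial <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("value", "genotype", "treatment") %in% names(data)))
  if (any(!is.finite(data$value))) stop("values must be finite", call. = FALSE)
  g <- factor(data$genotype)
  t <- factor(data$treatment)
  if (nlevels(g) != 2L || nlevels(t) != 2L) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  counts <- table(g, t)
  if (any(counts < 2L)) {
    stop("every genotype x treatment cell needs at least 2 observations",
         call. = FALSE)
  }
  list(y = data$value, g = g, t = t)
}

#' Type-III two-way ANOVA for the 2 x 2 design
#'
#' Decomposes the peak-pressure or enhancement values into genotype,
#' treatment and interaction effects with Type-III (marginal) sums of
#' squares, the convention appropriate for the unbalanced cell sizes of a
#' 21-24 foci-per-group design. Each term's SS is the increase in residual
#' SS when that term's effect-coded column is dropped from the full
#' cell-means model; F-ratios use the residual mean square. Degenerate data
#' with zero between- and within-cell variance report F = 0, p = 1.
#'
#' @param data data frame with columns `value`, `genotype`, `treatment`.
#' @return an `anova2x2`: list with `table` (data frame of `term`, `ss`,
#'   `df`, `f`, `p`), `ss_total` and `df_residual`.
#' @export
#' @examples
#' d <- generate_threshold_samples(seed = 1)
#' two_way_anova(d)
two_way_anova <- function(data) {
  fd <- .check_factorial(data)
  y <- fd$y
  a <- ifelse(fd$g == levels(fd$g)[1], 1, -1)
  b <- ifelse(fd$t == levels(fd$t)[1], 1, -1)
  X <- cbind(intercept = 1, a = a, b = b, ab = a * b)
  rss <- function(cols) {
    fit <- stats::lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(1:4)
  ss <- c(genotype    = rss(c(1, 3, 4)) - rss_full,
          treatment   = rss(c(1, 2, 4)) - rss_full,
          interaction = rss(c(1, 2, 3)) - rss_full)
  ss[ss < 0] <- 0  # guard against roundoff
  df_res <- length(y) - 4L
  ms_res <- rss_full / df_res
  f <- p <- numeric(3)
  for (i in 1:3) {
    if (ss[i] <= .Machine$double.eps * max(1, sum(y^2))) {
      f[i] <- 0; p[i] <- 1
    } else if (ms_res == 0) {
      f[i] <- Inf; p[i] <- 0
    } else {
      f[i] <- ss[i] / ms_res
      p[i] <- stats::pf(f[i], 1, df_res, lower.tail = FALSE)
    }
  }
  tab <- data.frame(
    term = c(names(ss), "residual"),
    ss = c(unname(ss), rss_full),
    df = c(1L, 1L, 1L, df_res),
    f = c(f, NA_real_),
    p = c(p, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 ss_total = sum((y - mean(y))^2),
                 df_residual = df_res),
            class = "anova2x2")
}

#' @export
print.anova2x2 <- function(x, ...) {
  cat("Type-III two-way ANOVA (2 x 2)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey-Kramer honest significant differences over the four cells
#'
#' All six pairwise comparisons among the genotype x treatment cells,
#' adjusted with the studentized-range distribution. Unequal cell sizes use
#' the Tukey-Kramer standard error `sqrt(MSE/2 * (1/ni + 1/nj))`; the error
#' mean square is the pooled within-cell variance of the full cell-means
#' model (the same residual as [two_way_anova()]).
#'
#' @param data data frame with columns `value`, `genotype`, `treatment`.
#' @param alpha significance level used for the `significant` flag.
#' @return data frame with columns `comparison`, `diff`, `se`, `q`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(data, alpha = 0.05) {
  fd <- .check_factorial(data)
  cell <- interaction(fd$g, fd$t, sep = ":", drop = FALSE)
  means <- tapply(fd$y, cell, mean)
  ns <- tapply(fd$y, cell, length)
  k <- length(means)
  df_res <- length(fd$y) - k
  mse <- sum((fd$y - stats::ave(fd$y, cell))^2) / df_res
  combs <- utils::combn(names(means), 2L)
  rows <- apply(combs, 2L, function(pair) {
    i <- pair[1]; j <- pair[2]
    diff <- means[[j]] - means[[i]]
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    data.frame(comparison = paste(j, "-", i), diff = diff, se = se,
               q = q, p_adj = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: `G = max |x - mean| / sd` (sample SD), compared
#' with the t-based critical value
#' `G_crit = ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is
#' the upper `alpha / (2n)` quantile of the t distribution on `n - 2`
#' degrees of freedom. A constant sample has no outlier by convention.
#'
#' @param values numeric vector, `n >= 3`, finite.
#' @param alpha significance level.
#' @return list with `is_outlier`, `g`, `critical`, `index` (of the most
#'   extreme value), `n`, `alpha`.
#' @export
#' @examples
#' grubbs_test(c(-1, 0, 1))
#' grubbs_test(c(0, 0, 0, 100))
grubbs_test <- function(values, alpha = 0.05) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  if (n < 3L) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) {
    return(list(is_outlier = FALSE, g = NA_real_, critical = NA_real_,
                index = NA_integer_, n = n, alpha = alpha))
  }
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  g <- dev[idx] / s
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(is_outlier = g > crit, g = g, critical = crit, index = idx,
       n = n, alpha = alpha)
}
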
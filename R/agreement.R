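#' Paired measurement series from two methods
#'
#' Carrier for two paired series of lesion-area measurements (method A and
#' method B, e.g. two radiologists, or a radiologist and the region-growing
#' pipeline).
#'
#' @param x,y numeric vectors of mm^2 values, equal length >= 3, all finite.
#' @param labels optional lesion/image identifiers.
#' @return an object of class `paired_series`.
#' @export
paired_series <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("paired series needs at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("all values must be finite")
  if (is.null(labels)) labels <- as.character(seq_along(x))
  if (length(labels) != length(x)) stop("labels length must match x and y")
  structure(list(labels = as.character(labels), x = as.numeric(x),
                 y = as.numeric(y)), class = "paired_series")
}

series_xy <- function(series, y = NULL) {
  if (inherits(series, "paired_series")) list(x = series$x, y = series$y)
  else list(x = as.numeric(series), y = as.numeric(y))
}

# all permutations of 1..n in lexicographic order (n <= 9 in practice)
perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of ranks (average ranks for ties). The
#' p-value is two-sided: for n >= 10 from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom, and
#' for n < 10 from the exact permutation distribution of rho.
#'
#' @param series a [paired_series()], or a numeric vector (then supply `y`).
#' @param y second series when `series` is a plain vector.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(series, y = NULL) {
  s <- series_xy(series, y)
  n <- length(s$x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0)
    stop("rho is undefined for a constant series")
  rx <- rank(s$x); ry <- rank(s$y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  } else {
    pm <- perms(n)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    rho_all <- (matrix(ry_c[pm], nrow(pm), n) %*% rx_c) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Lin's concordance correlation coefficient with 95% CI
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, per Lin's original estimator (sample 1/(n-1)
#' moments change the value at small n). The default 95% CI applies the
#' Fisher z transform with Lin's asymptotic variance and back-transforms;
#' `ci = "bootstrap"` gives a percentile bootstrap instead.
#'
#' @param series a [paired_series()] or numeric vector (then supply `y`).
#' @param y second series when `series` is a plain vector.
#' @param conf confidence level (default 0.95).
#' @param ci "fisher" (default) or "bootstrap".
#' @param boot_n bootstrap replicates when `ci = "bootstrap"`.
#' @param boot_seed seed for the bootstrap resampling.
#' @return list with `ccc`, `ci_low`, `ci_high`, `n`, `ci_method`.
#' @export
lin_ccc <- function(series, y = NULL, conf = 0.95, ci = c("fisher", "bootstrap"),
                    boot_n = 2000, boot_seed = 1L) {
  ci <- match.arg(ci)
  s <- series_xy(series, y)
  n <- length(s$x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0)
    stop("ccc is undefined for a constant series")
  est <- ccc_point(s$x, s$y)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci == "fisher") {
    r <- stats::cor(s$x, s$y)
    cc <- est$ccc
    u <- est$u
    # Lin's asymptotic variance of the z-transformed ccc
    se2 <- ((1 - r^2) * cc^2 / ((1 - cc^2) * r^2) +
            2 * cc^3 * (1 - cc) * u^2 / (r * (1 - cc^2)^2) -
            cc^4 * u^4 / (2 * r^2 * (1 - cc^2)^2)) / (n - 2)
    z <- atanh(cc)
    lo <- tanh(z - zq * sqrt(se2))
    hi <- tanh(z + zq * sqrt(se2))
  } else {
    cc_b <- with_seed(boot_seed, vapply(seq_len(boot_n), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- s$x[idx]; yb <- s$y[idx]
      if (stats::sd(xb) == 0 || stats::sd(yb) == 0) return(NA_real_)
      ccc_point(xb, yb)$ccc
    }, 0))
    qs <- stats::quantile(cc_b, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(ccc = est$ccc, ci_low = lo, ci_high = hi, n = n, ci_method = ci)
}

ccc_point <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  list(ccc = 2 * cxy / (vx + vy + (mx - my)^2),
       u = (mx - my) / sqrt(sqrt(vx) * sqrt(vy)))
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are `x - y` by default (method A minus method B); the sign
#' convention is recorded in the output so it is never ambiguous. Bias is
#' the mean difference, `sd_diff` the sample (n-1) standard deviation of the
#' differences, and the limits are `bias +/- 1.96 sd_diff`. Per-point means
#' and differences are returned for plotting.
#'
#' @param series a [paired_series()] or numeric vector (then supply `y`).
#' @param y second series when `series` is a plain vector.
#' @param direction "x-y" (default) or "y-x".
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`,
#'   `direction`, and `points` (data.frame of mean/diff per pair).
#' @export
bland_altman <- function(series, y = NULL, direction = c("x-y", "y-x")) {
  direction <- match.arg(direction)
  s <- series_xy(series, y)
  n <- length(s$x)
  if (n < 2) stop("need at least 2 paired observations")
  d <- if (direction == "x-y") s$x - s$y else s$y - s$x
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
       sd_diff = sd_d, n = n, direction = direction,
       points = data.frame(mean = (s$x + s$y) / 2, diff = d))
}

#' Full method-agreement validation
#'
#' Assembles the three-part agreement analysis between two paired
#' measurement series: Spearman correlation (with significance at
#' `p <= alpha`), Lin's concordance correlation coefficient with 95% CI, and
#' Bland-Altman bias with 95% limits of agreement. Optionally renders a
#' scatter plot with the identity line and a Bland-Altman plot to PNG files,
#' together with a CSV of plot coordinates so results stay testable without
#' graphics.
#'
#' @param series a [paired_series()].
#' @param alpha significance level for the Spearman p (default 0.05).
#' @param plot_dir directory for `scatter.png`, `bland_altman.png`,
#'   `plot_data.csv`; `NULL` (default) skips file output.
#' @param direction Bland-Altman difference direction, see [bland_altman()].
#' @return an object of class `agreement_result`.
#' @export
validate_agreement <- function(series, alpha = 0.05, plot_dir = NULL,
                               direction = "x-y") {
  stopifnot(inherits(series, "paired_series"))
  sp <- spearman(series)
  cc <- lin_ccc(series)
  ba <- bland_altman(series, direction = direction)
  res <- structure(list(
    n = sp$n, spearman_rho = sp$rho, spearman_p = sp$p,
    spearman_method = sp$method, significant = sp$p <= alpha, alpha = alpha,
    ccc = cc$ccc, ccc_ci_low = cc$ci_low, ccc_ci_high = cc$ci_high,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    sd_diff = ba$sd_diff, direction = ba$direction,
    series = series, points = ba$points), class = "agreement_result")
  if (!is.null(plot_dir)) {
    if (!dir.exists(plot_dir)) dir.create(plot_dir, recursive = TRUE)
    grDevices::png(file.path(plot_dir, "scatter.png"), 640, 640)
    plot(res, which = "scatter")
    grDevices::dev.off()
    grDevices::png(file.path(plot_dir, "bland_altman.png"), 640, 640)
    plot(res, which = "bland_altman")
    grDevices::dev.off()
    utils::write.csv(cbind(label = series$labels, method_a_mm2 = series$x,
                           method_b_mm2 = series$y, ba$points),
                     file.path(plot_dir, "plot_data.csv"), row.names = FALSE)
  }
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d pairs\n", x$n))
  cat(sprintf("  Spearman rho %.3f (p = %.4g, %s)%s\n", x$spearman_rho,
              x$spearman_p, x$spearman_method,
              if (x$significant) sprintf(" [significant at %.2g]", x$alpha) else ""))
  cat(sprintf("  Lin's CCC %.3f (95%% CI %.3f-%.3f)\n",
              x$ccc, x$ccc_ci_low, x$ccc_ci_high))
  cat(sprintf("  Bland-Altman (%s) bias %.3f mm^2, 95%% LoA %.3f to %.3f mm^2\n",
              x$direction, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @param which "scatter", "bland_altman", or "both" (default, side by side).
#' @rdname validate_agreement
#' @export
plot.agreement_result <- function(x, which = c("both", "scatter", "bland_altman"),
                                  ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "scatter")) {
    rng <- range(c(x$series$x, x$series$y))
    graphics::plot(x$series$x, x$series$y, xlim = rng, ylim = rng,
                   xlab = "method A area (mm^2)", ylab = "method B area (mm^2)",
                   main = sprintf("rho = %.2f, CCC = %.2f", x$spearman_rho, x$ccc),
                   pch = 19, col = "steelblue")
    graphics::abline(0, 1, col = "darkgreen")
  }
  if (which %in% c("both", "bland_altman")) {
    graphics::plot(x$points$mean, x$points$diff,
                   xlab = "mean of methods (mm^2)",
                   ylab = sprintf("difference %s (mm^2)", x$direction),
                   main = sprintf("bias = %.2f [%.2f, %.2f]",
                                  x$bias, x$loa_low, x$loa_high),
                   pch = 19, col = "steelblue",
                   ylim = range(c(x$points$diff, x$loa_low, x$loa_high)))
    graphics::abline(h = x$bias, col = "purple")
    graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  }
  invisible(x)
}

#' Read a paired series from CSV
#'
#' Expects columns `label`, `method_a_mm2`, `method_b_mm2`.
#'
#' @param path CSV file path.
#' @return a [paired_series()].
#' @export
read_paired_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "method_a_mm2", "method_b_mm2")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  paired_series(df$method_a_mm2, df$method_b_mm2, df$label)
}
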
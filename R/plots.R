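#' Fitted mixture density
#'
#' Evaluates the fitted three-component mixture density (or a single
#' weighted component, \eqn{\epsilon_j \phi(x; \mu_j, \sigma_j)}) at
#' `x`.  Each weighted component integrates to its mixture proportion;
#' the total integrates to 1.
#'
#' @param fit an `empnull_fit` from [gibbs_fit], or a
#'   [mixture_parameters] object.
#' @param x numeric evaluation points.
#' @param component `"all"` for the full mixture, or 1, 2, 3 for the
#'   null, negative, positive component.
#' @return numeric densities at `x`.
#' @export
mixture_density <- function(fit, x, component = "all") {
  params <- if (inherits(fit, "empnull_fit")) fit$params
            else if (inherits(fit, "mixture_parameters")) fit
            else stop("fit must be an 'empnull_fit' or 'mixture_parameters'")
  if (identical(component, "all")) {
    rowSums(vapply(1:3, function(j) {
      params$proportions[j] * stats::dnorm(x, params$means[j], params$sds[j])
    }, numeric(length(x))))
  } else {
    j <- as.integer(component)
    if (is.na(j) || j < 1L || j > 3L) stop("component must be 'all', 1, 2 or 3")
    params$proportions[j] * stats::dnorm(x, params$means[j], params$sds[j])
  }
}

#' Diagnostic plots for an empirical-null fit
#'
#' Two panels: a histogram of the statistics with the fitted mixture
#' overlaid (total in black, null component in red, negative/positive
#' alternative components in blue and green), and a QQ-plot of observed
#' versus expected -log10 p-values under the standard normal, before
#' (grey) and after (black) empirical-null correction.
#'
#' @param fit an `empnull_fit` from [gibbs_fit].
#' @param file optional output path; its extension selects the device
#'   (`.png` or `.svg`).  When `NULL`, plots go to the active device.
#' @param width,height device size in inches.
#' @return `file` (or `NULL`), invisibly.
#' @export
diagnostic_plots <- function(fit, file = NULL, width = 10, height = 5) {
  if (!inherits(fit, "empnull_fit"))
    stop("diagnostic plots require a completed fit (an 'empnull_fit' object)")
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = width, height = height,
                                units = "in", res = 150),
           svg = grDevices::svg(file, width = width, height = height),
           stop("unsupported plot format '", ext, "'; use .png or .svg"))
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  z <- fit$z
  xs <- seq(min(z) - 1, max(z) + 1, length.out = 512)
  graphics::hist(z, breaks = "FD", freq = FALSE, col = "grey90",
                 border = "grey70", main = "Statistics and fitted mixture",
                 xlab = "z")
  graphics::lines(xs, mixture_density(fit, xs), col = "black", lwd = 2)
  graphics::lines(xs, mixture_density(fit, xs, 1), col = "red", lwd = 2)
  graphics::lines(xs, mixture_density(fit, xs, 2), col = "blue", lwd = 1.5)
  graphics::lines(xs, mixture_density(fit, xs, 3), col = "green4", lwd = 1.5)
  graphics::legend("topright", bty = "n", lwd = c(2, 2, 1.5, 1.5),
                   col = c("black", "red", "blue", "green4"),
                   legend = c("mixture", sprintf("null (%.2f, %.2f)",
                                                 fit$null$bias,
                                                 fit$null$inflation),
                              "negative", "positive"))
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_cor <- empirical_null_correct(z, fit$null)$p_value
  n <- length(z)
  expected <- -log10(stats::ppoints(n))
  graphics::plot(expected, sort(-log10(p_raw), decreasing = TRUE),
                 col = "grey60", pch = 16, cex = 0.4,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = "QQ-plot")
  graphics::points(expected, sort(-log10(p_cor), decreasing = TRUE),
                   col = "black", pch = 16, cex = 0.4)
  graphics::abline(0, 1, col = "red")
  graphics::legend("topleft", bty = "n", pch = 16,
                   col = c("grey60", "black"),
                   legend = c("uncorrected", "corrected"))
  invisible(file)
}

#' @export
plot.empnull_fit <- function(x, ...) {
  diagnostic_plots(x, file = NULL)
  invisible(x)
}
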
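#' Partial dependence of an NTCP model
#'
#' Average model response as one (or two) features sweep a grid: for each
#' grid value the feature is set to that value in every patient row
#' (interaction columns are recomputed from the modified row, using the
#' training standardization), predictions are made for all rows and
#' averaged. The grid spans the 1st-99th percentile of the observed
#' feature; the observed percentiles (1..99) are kept as rug marks so
#' plots show where data actually lie. In models with an interaction the
#' profile need not be monotone - a parabolic MD profile is the signature
#' of an MD-by-GRADX interaction.
#'
#' @param fit An [ntcp_fit()].
#' @param features One or two main-effect term names present in the
#'   model (e.g. `"md"` or `c("md", "gradx")`).
#' @param data Rows to average over; defaults to the training cohort.
#' @param grid_size Grid points per feature.
#' @return An object of class `pd_grid`: list with `features`, `grid`
#'   (data.frame of grid coordinates), `pd` (mean predicted probability
#'   per grid point), and `rug` (observed percentiles per feature).
#' @export
partial_dependence <- function(fit, features, data = NULL, grid_size = 50) {
  stopifnot(inherits(fit, "ntcp_fit"))
  if (is.null(data)) data <- fit$data
  mains <- split_terms(fit$terms)$mains
  if (!length(features) %in% 1:2)
    stop("`features` must name 1 or 2 features")
  if (!all(features %in% mains))
    stop("feature(s) not in the model: ",
         paste(setdiff(features, mains), collapse = ", "))
  cols <- .term_columns[features]
  axes <- lapply(cols, function(cl) {
    rng <- stats::quantile(data[[cl]], c(0.01, 0.99), names = FALSE)
    seq(rng[1], rng[2], length.out = grid_size)
  })
  names(axes) <- features
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  pd <- vapply(seq_len(nrow(grid)), function(k) {
    nd <- data
    for (f in features) nd[[.term_columns[f]]] <- grid[[f]][k]
    mean(predict(fit, newdata = nd, type = "response"))
  }, numeric(1))
  rug <- lapply(cols, function(cl)
    stats::quantile(data[[cl]], (1:99) / 100, names = FALSE))
  names(rug) <- features
  structure(list(features = features, grid = grid, pd = pd, rug = rug,
                 grid_size = grid_size),
            class = "pd_grid")
}

#' @export
print.pd_grid <- function(x, ...) {
  cat("Partial dependence over", paste(x$features, collapse = " x "),
      "(", length(x$pd), "grid points )\n")
  cat(sprintf("  mean probability range [%.4f, %.4f]\n",
              min(x$pd), max(x$pd)))
  invisible(x)
}

#' Plot a partial dependence profile
#'
#' 1D profiles are drawn as a line with rug marks at the observed
#' percentiles; 2D profiles as a filled image with contour lines and rug
#' marks on both axes.
#'
#' @param x A [partial_dependence()] result.
#' @param ... Passed to the underlying base plotting call.
#' @export
plot.pd_grid <- function(x, ...) {
  lab <- c(md = "MD [Gy]", gradx = "GRADX [Gy/mm]", pgm = "PGM [mm]")
  if (length(x$features) == 1L) {
    f <- x$features
    graphics::plot(x$grid[[f]], x$pd, type = "l", lwd = 2,
                   xlab = lab[[f]], ylab = "mean predicted probability",
                   ...)
    graphics::rug(x$rug[[f]])
  } else {
    f1 <- x$features[1]; f2 <- x$features[2]
    z <- matrix(x$pd, nrow = x$grid_size)
    xs <- unique(x$grid[[f1]]); ys <- unique(x$grid[[f2]])
    graphics::image(xs, ys, z, col = grDevices::hcl.colors(30, "YlOrRd",
                                                           rev = TRUE),
                    xlab = lab[[f1]], ylab = lab[[f2]], ...)
    graphics::contour(xs, ys, z, add = TRUE)
    graphics::rug(x$rug[[f1]], side = 1)
    graphics::rug(x$rug[[f2]], side = 2)
  }
  invisible(x)
}
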
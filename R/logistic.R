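# ---- term language -------------------------------------------------------
# Model terms are short names referring to cohort-table columns; an
# interaction "a:b" is the product of the (standardized) main-effect
# columns. The three canonical nested NTCP models are named shortcuts.

.term_columns <- c(md = "md_gy", gradx = "gradx_gy_per_mm", pgm = "pgm_mm")

#' Canonical NTCP model terms
#'
#' The three nested logistic models investigated for G2 xerostomia:
#' mean dose alone (`"md"`); mean dose, lateral gradient and their
#' interaction (`"md_gradx"`); and the same plus parotid gland migration
#' (`"md_gradx_pgm"`).
#'
#' @param model One of `"md"`, `"md_gradx"`, `"md_gradx_pgm"`.
#' @return Character vector of model terms.
#' @export
canonical_model_terms <- function(model = c("md_gradx_pgm", "md_gradx", "md")) {
  switch(match.arg(model),
         md = "md",
         md_gradx = c("md", "gradx", "md:gradx"),
         md_gradx_pgm = c("md", "gradx", "md:gradx", "pgm"))
}

split_terms <- function(terms) {
  parts <- strsplit(terms, ":", fixed = TRUE)
  mains <- unique(unlist(parts))
  unknown <- setdiff(mains, names(.term_columns))
  if (length(unknown) > 0L)
    stop("unknown model term(s): ", paste(unknown, collapse = ", "))
  list(parts = parts, mains = mains)
}

# Standardization parameters (means/sds of main-effect columns) and the
# design matrix (no intercept column). Interactions are products of the
# standardized mains, so `std` must come from the TRAINING data.
design_std <- function(data, mains, standardize = TRUE) {
  cols <- .term_columns[mains]
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  m <- vapply(cols, function(cl) {
    v <- data[[cl]]
    if (anyNA(v) || any(!is.finite(v))) stop("missing values in column ", cl)
    if (standardize) mean(v) else 0
  }, numeric(1))
  s <- vapply(cols, function(cl) {
    if (!standardize) return(1)
    sv <- stats::sd(data[[cl]])
    if (!is.finite(sv) || sv == 0)
      stop("column ", cl, " is constant; cannot standardize")
    sv
  }, numeric(1))
  list(mean = stats::setNames(m, mains), sd = stats::setNames(s, mains))
}

build_design <- function(data, terms, std) {
  sp <- split_terms(terms)
  z <- vapply(sp$mains, function(tm) {
    (data[[.term_columns[tm]]] - std$mean[tm]) / std$sd[tm]
  }, numeric(nrow(data)))
  z <- matrix(z, nrow = nrow(data),
              dimnames = list(NULL, sp$mains))
  X <- vapply(sp$parts, function(p) {
    if (length(p) == 1L) z[, p] else apply(z[, p, drop = FALSE], 1, prod)
  }, numeric(nrow(data)))
  matrix(X, nrow = nrow(data), dimnames = list(NULL, terms))
}

# ---- penalized IRLS core --------------------------------------------------
# Newton-Raphson for the (optionally ridge-penalized) logistic
# log-likelihood. The penalty is (n * lambda / 2) * sum(beta_j^2) over the
# slopes (intercept unpenalized), i.e. lambda is on the per-observation
# scale. Warm starts make leave-pair-out refits cheap.
logistic_irls <- function(X1, y, ridge = 0, beta = NULL,
                          tol = 1e-9, maxit = 50L) {
  p <- ncol(X1)
  if (is.null(beta)) beta <- numeric(p)
  pen <- c(0, rep(ridge, p - 1L)) * nrow(X1)
  converged <- FALSE
  mu <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    g <- drop(crossprod(X1, y - mu)) - pen * beta
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # dampen overly large Newton steps (separation makes them explode)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X1 %*% beta)
  mu <- stats::plogis(eta)
  separated <- all(abs(y - mu) < 1e-4)
  list(beta = beta, converged = converged, separated = separated,
       mu = mu, eta = eta,
       hessian = {
         w <- pmax(mu * (1 - mu), 1e-12)
         H <- crossprod(X1 * w, X1); diag(H) <- diag(H) + pen; H
       })
}

# ---- user-facing fit ------------------------------------------------------

#' Fit a logistic NTCP model of G2 xerostomia
#'
#' Fits a logistic regression of the binary xerostomia endpoint on the
#' requested dose/migration terms. Main-effect features are z-scored on
#' the training data and interaction columns are products of the
#' standardized mains, which keeps the small-sample fit well conditioned
#' and makes coefficients comparable across terms. With
#' `ridge_lambda = 0` the fit is maximum likelihood and perfect
#' separation raises an error suggesting a small ridge penalty; with
#' `ridge_lambda > 0` the slopes are L2-penalized (per-observation
#' scale; the intercept is never penalized).
#'
#' @param data Cohort table: a data.frame with a 0/1 `label` column and
#'   the feature columns `md_gy`, `gradx_gy_per_mm`, `pgm_mm` (as needed
#'   by the terms).
#' @param model Canonical model shortcut, see [canonical_model_terms()].
#'   Ignored when `terms` is given.
#' @param terms Explicit character vector of terms, e.g.
#'   `c("md", "gradx", "md:gradx")`.
#' @param standardize Z-score main-effect columns before fitting.
#' @param ridge_lambda Non-negative L2 penalty on the slopes.
#' @return An object of class `ntcp_fit` with `print`, `summary`,
#'   `coef`, `predict`, `simulate`, `residuals`, `logLik` and `plot`
#'   methods.
#' @examples
#' sim <- simulate_cohort(cohort_sim_config(n_patients = 200, seed = 7))
#' fit <- ntcp_fit(sim$cohort, model = "md_gradx_pgm")
#' summary(fit)
#' head(predict(fit, type = "response"))
#' @export
ntcp_fit <- function(data, model = "md_gradx_pgm", terms = NULL,
                     standardize = TRUE, ridge_lambda = 0) {
  if (is.null(terms)) terms <- canonical_model_terms(model)
  if (!is.data.frame(data) || !"label" %in% names(data))
    stop("`data` must be a cohort table with a `label` column")
  y <- data$label
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("`label` must be 0/1 with no missing values")
  if (length(unique(y)) < 2L)
    stop("all labels are identical; a logistic model cannot be fit")
  if (!is.numeric(ridge_lambda) || ridge_lambda < 0)
    stop("`ridge_lambda` must be >= 0")
  sp <- split_terms(terms)
  std <- design_std(data, sp$mains, standardize)
  X <- build_design(data, terms, std)
  X1 <- cbind("(Intercept)" = 1, X)
  fit <- logistic_irls(X1, y, ridge = ridge_lambda)
  if (ridge_lambda == 0 && (fit$separated || !fit$converged))
    stop("perfect separation / non-convergence at ridge_lambda = 0; ",
         "refit with a small ridge penalty (e.g. ridge_lambda = 0.01)")
  if (any(!is.finite(fit$beta)))
    stop("logistic fit produced non-finite coefficients")
  vcov <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  ll <- sum(stats::dbinom(y, 1, fit$mu, log = TRUE))
  structure(
    list(coefficients = stats::setNames(fit$beta, colnames(X1)),
         terms = terms, standardize = standardize, std = std,
         ridge_lambda = ridge_lambda, converged = fit$converged,
         n = length(y), n_pos = sum(y), loglik = ll, vcov = vcov,
         fitted = fit$mu, data = data, call = match.call()),
    class = "ntcp_fit"
  )
}

#' @export
print.ntcp_fit <- function(x, digits = 4, ...) {
  cat("Logistic NTCP model: label ~", paste(x$terms, collapse = " + "), "\n")
  cat(sprintf("n = %d (%d events)%s\n", x$n, x$n_pos,
              if (x$ridge_lambda > 0)
                sprintf(", ridge lambda = %g", x$ridge_lambda) else ""))
  cat("Coefficients (standardized scale):\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.ntcp_fit <- function(object, ...) object$coefficients

#' @export
logLik.ntcp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
vcov.ntcp_fit <- function(object, ...) object$vcov

#' @export
summary.ntcp_fit <- function(object, ...) {
  se <- if (is.null(object$vcov)) rep(NA_real_, length(object$coefficients))
        else sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.ntcp_fit")
}

#' @export
print.summary.ntcp_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlog-likelihood: %.3f  (AIC %.2f)\n", x$fit$loglik,
              -2 * x$fit$loglik + 2 * length(x$fit$coefficients)))
  if (x$fit$ridge_lambda > 0)
    cat("Note: penalized fit; standard errors are from the penalized",
        "information and approximate.\n")
  invisible(x)
}

#' Predict complication probabilities from an NTCP fit
#'
#' @param object An [ntcp_fit()].
#' @param newdata Optional data.frame with the model's feature columns;
#'   defaults to the training cohort. Standardization uses the training
#'   means/sds.
#' @param type `"response"` for probabilities, `"link"` for log-odds.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ntcp_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  X <- build_design(newdata, object$terms, object$std)
  eta <- drop(cbind(1, X) %*% object$coefficients)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.ntcp_fit <- function(object,
                               type = c("deviance", "pearson", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$data$label
  mu <- object$fitted
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu * (1 - mu)),
         deviance = sign(y - mu) *
           sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu))))
}

#' Simulate endpoint labels from a fitted NTCP model
#'
#' Draws Bernoulli outcomes at the fitted (or newdata) complication
#' probabilities, following the [stats::simulate()] contract.
#'
#' @param object An [ntcp_fit()].
#' @param nsim Number of simulated label vectors.
#' @param seed Optional RNG seed (restores the RNG state afterwards).
#' @param newdata Optional data.frame of features.
#' @param ... Unused.
#' @return data.frame with `nsim` columns of 0/1 labels.
#' @export
simulate.ntcp_fit <- function(object, nsim = 1, seed = NULL,
                              newdata = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- predict(object, newdata = newdata, type = "response")
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ntcp_fit <- function(x, feature = NULL, grid_size = 50, ...) {
  mains <- split_terms(x$terms)$mains
  if (is.null(feature)) feature <- mains[1]
  plot(partial_dependence(x, feature, grid_size = grid_size), ...)
}
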
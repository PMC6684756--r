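#' Mann-Whitney AUC of a score
#'
#' Fraction of positive-negative pairs ranked concordantly with the risk
#' direction, with ties counting 1/2 (the rank-sum estimator of the area
#' under the ROC curve). Flipping the risk direction maps the AUC to its
#' complement: `auc(higher) + auc(lower) = 1`, so an AUC below 0.5 for a
#' "higher is risky" feature is the same evidence as its complement for
#' the reversed risk factor.
#'
#' @param scores Numeric score per subject.
#' @param labels 0/1 endpoint labels; both classes must be present.
#' @param direction `"higher"` if larger scores indicate higher risk,
#'   `"lower"` for the reversed risk factor.
#' @return AUC in `[0, 1]`.
#' @examples
#' mann_whitney_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))  # 0.875
#' @export
mann_whitney_auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  if (!all(labels %in% c(0, 1))) stop("`labels` must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present to compute an AUC")
  r <- rank(scores)  # midranks handle ties exactly
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (direction == "lower") 1 - auc else auc
}

#' Leave-pair-out cross-validated AUC
#'
#' For every (positive i, negative j) patient pair, the model is refit on
#' the cohort with both held out (re-standardizing within each training
#' fold, so no information leaks) and the held-out pair is scored; the
#' pair contributes 1 if the positive scores higher, 1/2 on a tie, 0
#' otherwise. The AUC is the mean over all `n_pos * n_neg` pairs. This
#' estimator is nearly unbiased for small event counts, where
#' leave-one-out ROC estimates are badly biased.
#'
#' @inheritParams ntcp_fit
#' @param score_fun Optional scoring rule bypassing the logistic model:
#'   a `function(train, test)` returning one score per `test` row. A rule
#'   that ignores `train` reduces LPO-CV exactly to the Mann-Whitney AUC
#'   of its scores (a useful oracle).
#' @param on_error `"skip"` drops pairs whose inner fit fails (counted
#'   and warned about); `"abort"` re-raises the error.
#' @return An object of class `lpo_auc`: list with `auc`, `n_pos`,
#'   `n_neg`, `n_pairs`, `n_skipped`, `terms`.
#' @export
lpo_cv_auc <- function(data, model = "md_gradx_pgm", terms = NULL,
                       standardize = TRUE, ridge_lambda = 0,
                       score_fun = NULL, on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  if (is.null(terms)) terms <- canonical_model_terms(model)
  y <- data$label
  if (!all(y %in% c(0, 1))) stop("`label` must be 0/1")
  pos <- which(y == 1); neg <- which(y == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both outcome classes are required")
  use_model <- is.null(score_fun)
  if (use_model) {
    sp <- split_terms(terms)
    # warm start from the full-data fit (coefficients only; each fold
    # still re-estimates everything from its own training rows)
    std0 <- design_std(data, sp$mains, standardize)
    X1_all <- cbind(1, build_design(data, terms, std0))
    warm <- logistic_irls(X1_all, y, ridge = ridge_lambda)$beta
    raw <- vapply(sp$mains, function(tm) data[[.term_columns[tm]]],
                  numeric(nrow(data)))
    raw <- matrix(raw, nrow = nrow(data), dimnames = list(NULL, sp$mains))
    parts <- sp$parts
  }
  n_skipped <- 0L
  wins <- 0
  for (i in pos) {
    for (j in neg) {
      sc <- tryCatch({
        if (use_model) {
          keep <- setdiff(seq_along(y), c(i, j))
          tr <- raw[keep, , drop = FALSE]
          if (standardize) {
            mu <- colMeans(tr); sdv <- apply(tr, 2, stats::sd)
            if (any(sdv == 0)) stop("constant feature in training fold")
          } else { mu <- rep(0, ncol(tr)); sdv <- rep(1, ncol(tr)) }
          Ztr <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
          Xtr <- vapply(parts, function(p) {
            if (length(p) == 1L) Ztr[, p]
            else apply(Ztr[, p, drop = FALSE], 1, prod)
          }, numeric(length(keep)))
          fit <- logistic_irls(cbind(1, Xtr), y[keep],
                               ridge = ridge_lambda, beta = warm)
          if (any(!is.finite(fit$beta))) stop("non-finite inner fit")
          Zte <- sweep(sweep(raw[c(i, j), , drop = FALSE], 2, mu),
                       2, sdv, "/")
          Xte <- vapply(parts, function(p) {
            if (length(p) == 1L) Zte[, p]
            else apply(Zte[, p, drop = FALSE], 1, prod)
          }, numeric(2))
          drop(cbind(1, matrix(Xte, nrow = 2)) %*% fit$beta)
        } else {
          score_fun(data[-c(i, j), , drop = FALSE],
                    data[c(i, j), , drop = FALSE])
        }
      }, error = function(e) if (on_error == "abort") stop(e) else NULL)
      if (is.null(sc)) { n_skipped <- n_skipped + 1L; next }
      wins <- wins + (if (sc[1] > sc[2]) 1 else if (sc[1] == sc[2]) 0.5 else 0)
    }
  }
  n_pairs <- length(pos) * length(neg) - n_skipped
  if (n_skipped > 0L)
    warning(n_skipped, " leave-pair-out fold(s) failed and were skipped")
  if (n_pairs == 0L) stop("all leave-pair-out folds failed")
  structure(list(auc = wins / n_pairs, n_pos = length(pos),
                 n_neg = length(neg), n_pairs = n_pairs,
                 n_skipped = n_skipped, terms = terms),
            class = "lpo_auc")
}

#' @export
print.lpo_auc <- function(x, ...) {
  cat(sprintf("Leave-pair-out CV AUC = %.4f (%d x %d = %d pairs%s)\n",
              x$auc, x$n_pos, x$n_neg, x$n_pairs,
              if (x$n_skipped > 0) paste0(", ", x$n_skipped, " skipped")
              else ""))
  invisible(x)
}

#' Kendall rank concordance between paired features
#'
#' Kendall's tau-a by explicit pair counting (ties contribute zero to the
#' numerator; the denominator is all `n(n-1)/2` pairs), plus the
#' concordance probability `(1 + tau) / 2` - the chance that the two
#' features rank a random pair of patients the same way. Used as the
#' screen justifying modelling only the contralateral gland: if
#' ipsilateral and contralateral features are strongly concordant
#' (tau > 0.4, i.e. > 70% concordance), the second gland adds little.
#' `method = "tau-b"` applies the tie-corrected version via
#' [stats::cor()].
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`.
#' @param method `"tau-a"` (default) or `"tau-b"`.
#' @return List with `tau`, `concordance_prob`, `n`, `method`.
#' @examples
#' kendall_concordance(c(1, 2, 3), c(2, 1, 3))  # tau = 1/3
#' @export
kendall_concordance <- function(x, y, method = c("tau-a", "tau-b")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (method == "tau-b") {
    tau <- stats::cor(x, y, method = "kendall")
  } else {
    s <- 0
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      s <- s + sum(sign(x[i] - x[rest]) * sign(y[i] - y[rest]))
    }
    tau <- s / (n * (n - 1) / 2)
  }
  list(tau = tau, concordance_prob = (1 + tau) / 2, n = n, method = method)
}

#' Median split of the cohort on a feature, with per-stratum MD AUC
#'
#' Splits the cohort at the median of a feature (ties go to the low
#' stratum, so for distinct values and even n the strata have equal
#' size) and evaluates the univariate discrimination of the mean dose in
#' each stratum with the Mann-Whitney AUC under the conventional
#' "higher MD is risky" direction. Because an AUC below 0.5 simply means
#' the risk factor points the other way, the complement `1 - AUC` is
#' reported alongside. Strata in which one class is absent get `NA` AUCs
#' with a warning.
#'
#' @param data Cohort table with `label` and the feature columns.
#' @param feature Feature to split on (default `"gradx"`).
#' @param risk_feature Feature whose AUC is evaluated per stratum
#'   (default `"md"`).
#' @return An object of class `median_split`: list with the split
#'   feature, its median, and per-stratum summaries (`n`, `n_pos`,
#'   `auc`, `auc_flipped`, row indices).
#' @export
stratify_by_median <- function(data, feature = "gradx", risk_feature = "md") {
  fcol <- .term_columns[[feature]]
  rcol <- .term_columns[[risk_feature]]
  if (is.null(fcol) || is.null(rcol)) stop("unknown feature name")
  v <- data[[fcol]]
  if (is.null(v) || anyNA(v)) stop("feature column missing or has NAs")
  med <- stats::median(v)
  low <- which(v <= med); high <- which(v > med)
  if (length(low) == 0L || length(high) == 0L)
    stop("median split produced an empty stratum")
  stratum <- function(idx, name) {
    lab <- data$label[idx]
    if (length(unique(lab)) < 2L) {
      warning("stratum '", name, "' lacks one outcome class; AUC undefined")
      auc <- NA_real_
    } else {
      auc <- mann_whitney_auc(data[[rcol]][idx], lab, direction = "higher")
    }
    list(n = length(idx), n_pos = sum(lab), auc = auc,
         auc_flipped = 1 - auc, rows = idx)
  }
  structure(list(feature = feature, risk_feature = risk_feature,
                 median = med,
                 low = stratum(low, "low"), high = stratum(high, "high")),
            class = "median_split")
}

#' @export
print.median_split <- function(x, ...) {
  cat(sprintf("Median split on %s (median = %.4g)\n", x$feature, x$median))
  for (nm in c("low", "high")) {
    s <- x[[nm]]
    cat(sprintf(
      "  %-4s stratum: n = %d (%d events), AUC(%s, higher-risk) = %s",
      nm, s$n, s$n_pos, x$risk_feature,
      ifelse(is.na(s$auc), "NA", sprintf("%.3f", s$auc))))
    if (!is.na(s$auc) && s$auc < 0.5)
      cat(sprintf("  [flipped: %.3f for lower-%s risk]",
                  s$auc_flipped, x$risk_feature))
    cat("\n")
  }
  invisible(x)
}
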
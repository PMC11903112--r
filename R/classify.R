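# ROC cut-off derivation, the published median/IQR cut-off rule set, and
# multivariable logistic modelling of the pleomorphic-variant diagnosis.

#' Empirical ROC curve with Youden-optimal cut-off
#'
#' Builds the empirical ROC of a score against binary labels, using the
#' distinct score values as candidate thresholds (classification rule:
#' score strictly greater than threshold is called positive). The AUC is
#' the trapezoid area, which equals the Mann-Whitney pairwise concordance
#' probability with ties counted one half. The chosen cut-off maximises the
#' Youden index J = sensitivity + specificity - 1; ties are broken toward
#' the smallest threshold (highest sensitivity).
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical, or 0/1) of the same length;
#'   `TRUE`/1 is the positive class. Both classes must be present.
#' @return List of class `roc_result`: `auc`, `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `youden`),
#'   `chosen_threshold`, `chosen_sens`, `chosen_spec`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build an ROC curve")
  }
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) sum(scores > t & labels) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & !labels) / n_neg, numeric(1))
  # trapezoid over the full curve: prepend the (1,1) endpoint (t below all
  # scores); the t = max(scores) point is (0,0), so the curve is complete
  # and (fpr, tpr) descend monotonically as the threshold rises
  fpr <- c(1, 1 - spec)
  tpr <- c(1, sens)
  auc <- sum((fpr[-length(fpr)] - fpr[-1L]) *
               (tpr[-length(tpr)] + tpr[-1L]) / 2)
  youden <- sens + spec - 1
  best <- which.max(youden)  # which.max takes the first, i.e. smallest threshold
  structure(
    list(
      auc = auc,
      curve = tibble::tibble(
        threshold = thr, sensitivity = sens, specificity = spec,
        youden = youden
      ),
      chosen_threshold = thr[best],
      chosen_sens = sens[best],
      chosen_spec = spec[best]
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result AUC %.3f | cut-off %.4g (sens %.3f, spec %.3f)>\n",
    x$auc, x$chosen_threshold, x$chosen_sens, x$chosen_spec
  ))
  invisible(x)
}

#' Build a cut-off rule
#'
#' A decision rule of the form "case summary statistic strictly greater
#' than threshold" on one of the four size parameters.
#'
#' @param parameter `"area"`, `"perimeter"`, `"min_feret"` or `"max_feret"`.
#' @param statistic `"median"` or `"iqr"`.
#' @param threshold positive cut-off in the parameter's units.
#' @param note free-text provenance note.
#' @return One-row tibble with columns `parameter`, `statistic`,
#'   `threshold`, `direction`, `note`.
#' @export
cutoff_rule <- function(parameter, statistic, threshold, note = "") {
  parameter <- match.arg(parameter,
                         c("area", "perimeter", "min_feret", "max_feret"))
  statistic <- match.arg(statistic, c("median", "iqr"))
  stopifnot(is.numeric(threshold), threshold > 0)
  tibble::tibble(
    parameter = parameter, statistic = statistic,
    threshold = threshold, direction = "greater", note = note
  )
}

#' The published cut-off rule set for the pleomorphic variant
#'
#' The eight ROC-derived thresholds separating pleomorphic ILC from the
#' classic and solid variants: per-case medians of nuclear area
#' (> 48.2 um^2), perimeter (> 25.2 um), minimum Feret diameter (> 6.8 um)
#' and maximum Feret diameter (> 9.1 um), and the corresponding IQR
#' thresholds (> 19.4, > 5.3, > 1.5, > 2.2) capturing nuclear size
#' variability.
#'
#' @return Tibble of 8 [cutoff_rule()] rows.
#' @export
published_rules <- function() {
  rbind(
    cutoff_rule("area", "median", 48.2, "published median cut-off"),
    cutoff_rule("perimeter", "median", 25.2, "published median cut-off"),
    cutoff_rule("min_feret", "median", 6.8, "published median cut-off"),
    cutoff_rule("max_feret", "median", 9.1, "published median cut-off"),
    cutoff_rule("area", "iqr", 19.4, "published IQR cut-off"),
    cutoff_rule("perimeter", "iqr", 5.3, "published IQR cut-off"),
    cutoff_rule("min_feret", "iqr", 1.5, "published IQR cut-off"),
    cutoff_rule("max_feret", "iqr", 2.2, "published IQR cut-off")
  )
}

#' Apply cut-off rules to a case summary
#'
#' Evaluates each rule (statistic strictly greater than its threshold) on
#' one summary row and combines the per-rule flags into a single call.
#'
#' @param summary one row from [summarize_cases()].
#' @param rules tibble of [cutoff_rule()] rows.
#' @param combination how the flags combine into one call:
#'   `"single_parameter"` (default: the maximum-diameter median and IQR
#'   rules must both fire — the maximum diameter is the most influential
#'   parameter in the multivariable model), `"all_of"`, `"any_of"`, or
#'   `"vote_k"` (at least `k` flags).
#' @param k vote threshold for `combination = "vote_k"`.
#' @return List with `flags` (tibble of rule columns plus `value`, `flag`)
#'   and `call` (logical).
#' @export
apply_rules <- function(summary, rules,
                        combination = c("single_parameter", "all_of",
                                        "any_of", "vote_k"),
                        k = NULL) {
  combination <- match.arg(combination)
  stopifnot(nrow(summary) == 1L)
  cols <- paste0(rules$statistic, "_", rules$parameter)
  missing_cols <- setdiff(cols, names(summary))
  if (length(missing_cols)) {
    stop("summary lacks parameter(s): ", paste(missing_cols, collapse = ", "))
  }
  value <- vapply(cols, function(cn) summary[[cn]], numeric(1))
  flags <- rules
  flags$value <- unname(value)
  flags$flag <- flags$value > flags$threshold
  call <- switch(combination,
    single_parameter = {
      sel <- flags$parameter == "max_feret"
      if (!any(sel)) stop("no max_feret rule present for single_parameter")
      all(flags$flag[sel])
    },
    all_of = all(flags$flag),
    any_of = any(flags$flag),
    vote_k = {
      if (is.null(k)) stop("combination = 'vote_k' needs k")
      sum(flags$flag) >= k
    }
  )
  list(flags = flags, call = call)
}

#' Multivariable logistic regression with Wald intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()]) of a binary outcome on per-case nuclear parameters,
#' reporting odds ratios with Wald 95% confidence intervals and p-values,
#' the SPSS-style output clinical studies print. Features are used on their
#' raw scale (odds ratios per unit) unless `standardize` is set. Complete
#' or quasi-complete separation is detected and flagged rather than
#' silently returned.
#'
#' @param features data frame or matrix of numeric predictors (one row per
#'   case).
#' @param labels binary outcome vector.
#' @param standardize scale each feature to unit standard deviation first.
#' @return List of class `logit_model`: `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `odds_ratio`, `ci_lower`, `ci_upper`,
#'   `p_value`), `intercept`, `converged`, `separation`.
#' @export
fit_logistic <- function(features, labels, standardize = FALSE) {
  X <- as.data.frame(features)
  if (!nrow(X)) stop("no cases supplied")
  y <- as.numeric(as.logical(labels))
  if (length(unique(y)) < 2L) stop("need at least one case per class")
  const <- vapply(X, function(col) stats::var(col) == 0, logical(1))
  if (any(const)) {
    stop("constant feature(s): ", paste(names(X)[const], collapse = ", "))
  }
  if (standardize) X[] <- lapply(X, function(col) col / stats::sd(col))
  dat <- cbind(X, .y = y)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- stats::qnorm(0.975)
  terms <- rownames(sm)
  keep <- terms != "(Intercept)"
  separation <- sep_warned || any(abs(est[keep]) > 15 & se[keep] > 100)
  if (separation) {
    warning("possible complete separation; estimates are unreliable")
  }
  list_out <- structure(
    list(
      coefficients = tibble::tibble(
        term = terms[keep],
        estimate = unname(est[keep]),
        std_error = unname(se[keep]),
        odds_ratio = exp(unname(est[keep])),
        ci_lower = exp(unname(est[keep] - z * se[keep])),
        ci_upper = exp(unname(est[keep] + z * se[keep])),
        p_value = unname(sm[keep, "Pr(>|z|)"])
      ),
      intercept = unname(est["(Intercept)"]),
      converged = fit$converged,
      separation = separation
    ),
    class = "logit_model"
  )
  list_out
}

#' @export
print.logit_model <- function(x, ...) {
  cat(sprintf("<logit_model | converged: %s | separation: %s>\n",
              x$converged, x$separation))
  print(x$coefficients)
  invisible(x)
}
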
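# Group inference: descriptive tests, covariate screening, covariate-adjusted
# between-group comparison of percent changes, Holm step-down correction.

#' Descriptive two-group test
#'
#' Continuous variables: unpaired two-sample t-test (pooled variance by
#' default, Welch optionally). Categorical variables: chi-square test on the
#' group-by-level table (no continuity correction by default).
#'
#' @param x Variable values.
#' @param group Two-level grouping vector.
#' @param type `"continuous"` or `"categorical"`.
#' @param var_equal Pooled-variance t (default `TRUE`).
#' @param correct Continuity correction for the chi-square test.
#' @return List: `p_value`, `statistic`, and per-group summaries (mean (SD)
#'   for continuous, n (%) for categorical).
#' @export
descriptive_test <- function(x, group, type = c("continuous", "categorical"),
                             var_equal = TRUE, correct = FALSE) {
  type <- match.arg(type)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  keep <- complete.cases(x, group)
  x <- x[keep]; group <- droplevels(group[keep])
  if (type == "continuous") {
    if (any(table(group) < 2))
      stop("need at least 2 observations per group")
    if (sd(x) == 0) stop("variable is constant: test undefined")
    tt <- t.test(x ~ group, var.equal = var_equal)
    summ <- tapply(x, group, function(v)
      sprintf("%.2f (%.2f)", mean(v), sd(v)))
    list(p_value = tt$p.value, statistic = unname(tt$statistic),
         summaries = summ, test = if (var_equal) "pooled t" else "Welch t")
  } else {
    tab <- table(group, x)
    if (any(rowSums(tab) == 0) || ncol(tab) < 2)
      stop("categorical test needs nonzero margins and at least 2 levels")
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    summ <- apply(tab, 1, function(r)
      paste(sprintf("%d (%.1f%%)", r, 100 * r / sum(r)), collapse = ", "))
    list(p_value = ct$p.value, statistic = unname(ct$statistic),
         summaries = summ, test = "chi-square")
  }
}

#' Two-group pooled t-test from summary statistics
#'
#' For comparisons where only printed group means, SDs and sizes are
#' available.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return List: `p_value`, `statistic`, `df`.
#' @export
descriptive_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("both groups constant: test undefined")
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(p_value = 2 * pt(-abs(tstat), df), statistic = tstat, df = df)
}

#' Screen a covariate against the primary outcome
#'
#' Pearson correlation; the covariate is flagged for inclusion when p <
#' `alpha`. A zero-variance covariate is excluded with a warning rather than
#' an error (the degenerate-cohort case).
#'
#' @param covariate,outcome Paired numeric vectors (complete cases used).
#' @param alpha Inclusion threshold on the correlation p-value.
#' @param name Covariate label.
#' @return One-row data frame of class `covariate_screen`: `covariate`,
#'   `correlation_r`, `screen_p`, `included`.
#' @export
screen_covariate <- function(covariate, outcome, alpha = 0.05,
                             name = deparse(substitute(covariate))) {
  keep <- complete.cases(covariate, outcome)
  covariate <- as.numeric(covariate[keep]); outcome <- outcome[keep]
  if (length(covariate) < 3) stop("need at least 3 paired observations")
  if (sd(covariate) == 0) {
    warning("covariate '", name, "' has zero variance: excluded")
    out <- data.frame(covariate = name, correlation_r = NA_real_,
                      screen_p = NA_real_, included = FALSE)
  } else if (sd(outcome) == 0) {
    stop("outcome is constant: correlation undefined")
  } else {
    ct <- cor.test(covariate, outcome, method = "pearson")
    out <- data.frame(covariate = name,
                      correlation_r = unname(ct$estimate),
                      screen_p = ct$p.value,
                      included = ct$p.value < alpha)
  }
  class(out) <- c("covariate_screen", class(out))
  out
}

#' Covariate-adjusted between-group comparison
#'
#' Ordinary least squares of the outcome (a percent change) on group plus
#' covariates. Adjusted group means are the model predictions for each group
#' with covariates held at their grand sample mean (least-squares means), with
#' delta-method standard errors; the group p-value is the t-test of the group
#' coefficient. With no covariates this reduces exactly to the pooled-variance
#' two-sample t-test. Constant covariates are dropped with a warning;
#' collinear covariate sets are an error naming the aliased columns.
#'
#' @param data Data frame containing the variables.
#' @param outcome Name of the outcome column.
#' @param group Name of the two-level group column.
#' @param covariates Character vector of covariate column names (numeric or
#'   two-level factors, coded 0/1 internally).
#' @return Object of class `trab_adjustfit` with `print`, `summary` and
#'   `coef` methods: adjusted means and SEs per group, raw p, the fitted lm.
#' @export
adjusted_group_comparison <- function(data, outcome, group,
                                      covariates = character()) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            group %in% names(data), all(covariates %in% names(data)))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  y <- data[[outcome]]
  covs <- list()
  for (cv in covariates) {
    v <- data[[cv]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("covariate '", cv, "' is constant: dropped from the model")
      next
    }
    covs[[cv]] <- v
  }
  df <- data.frame(.y = y, .g = g)
  for (cv in names(covs)) df[[cv]] <- covs[[cv]]
  df <- df[complete.cases(df), ]
  n_per <- table(df$.g)
  if (any(n_per < length(covs) + 2))
    stop("insufficient observations per group (need at least ",
         length(covs) + 2, " per group)")
  rhs <- paste(c(".g", names(covs)), collapse = " + ")
  if (length(covs)) {
    X <- as.matrix(df[names(covs)])
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1) {
      aliased <- names(covs)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
      stop("collinear covariates: ", paste(aliased, collapse = ", "))
    }
  }
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  if (anyNA(coef(fit)))
    stop("collinear covariates: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  V <- vcov(fit)
  lv <- levels(df$.g)
  cov_means <- vapply(names(covs), function(cv) mean(df[[cv]]), numeric(1))
  adj <- lapply(lv, function(l) {
    nd <- data.frame(.g = factor(l, levels = lv))
    for (cv in names(covs)) nd[[cv]] <- cov_means[[cv]]
    mm <- model.matrix(stats::delete.response(stats::terms(fit)), nd)
    est <- unname(drop(mm %*% coef(fit)))
    se <- unname(sqrt(drop(mm %*% V %*% t(mm))))
    c(mean = est, se = se)
  })
  names(adj) <- lv
  sm <- summary(fit)$coefficients
  grow <- grep("^\\.g", rownames(sm))
  out <- list(outcome = outcome, group_levels = lv,
              adjusted_means = vapply(adj, `[[`, numeric(1), "mean"),
              adjusted_se = vapply(adj, `[[`, numeric(1), "se"),
              difference = unname(coef(fit)[grow]),
              raw_p = sm[grow, "Pr(>|t|)"],
              covariates = names(covs),
              n = as.vector(n_per), fit = fit)
  class(out) <- "trab_adjustfit"
  out
}

#' @export
print.trab_adjustfit <- function(x, ...) {
  cat(sprintf("Adjusted group comparison of %s (covariates: %s)\n",
              x$outcome,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  for (i in seq_along(x$group_levels))
    cat(sprintf("  %-10s adjusted mean %7.2f (SE %5.2f), n = %d\n",
                x$group_levels[i], x$adjusted_means[i], x$adjusted_se[i],
                x$n[i]))
  cat(sprintf("  group difference %.3f, p = %.4g\n", x$difference, x$raw_p))
  invisible(x)
}

#' @export
summary.trab_adjustfit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.trab_adjustfit <- function(object, ...) coef(object$fit, ...)

#' Holm step-down adjustment
#'
#' Step-down correction over a family of m comparisons: p-values are sorted
#' ascending, the i-th smallest is multiplied by (m - i + 1), running maxima
#' enforce monotonicity and values are capped at 1.
#'
#' @param p Numeric p-values in \[0, 1\], optionally named.
#' @param m Family size (default `length(p)`; may be larger when some
#'   comparisons are not supplied).
#' @return Adjusted p-values, same order and names as `p`.
#' @export
holm_adjust <- function(p, m = length(p)) {
  stopifnot(is.numeric(p), length(p) >= 1, .is_count(m))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  if (m < length(p)) stop("family size m cannot be below length(p)")
  out <- p.adjust(p, method = "holm", n = m)
  names(out) <- names(p)
  out
}

#' Table-style battery of adjusted group comparisons
#'
#' Runs [adjusted_group_comparison()] for each percent-change variable and
#' applies Holm step-down correction across the family (all nine variables by
#' default, the primary outcome included in the family).
#'
#' @param changes Data frame with one row per subject: `subject_id`, group
#'   and covariate columns, and `pct_<variable>` columns.
#' @param group Group column name.
#' @param covariates Covariate column names.
#' @param variables Profile variables to compare (default all nine).
#' @param m Holm family size (default the number of variables compared).
#' @return Data frame of class `trab_comparison`: per variable the adjusted
#'   group means (SE), raw p and Holm-adjusted p.
#' @export
compare_groups <- function(changes, group = "group",
                           covariates = character(),
                           variables = trab_variables(), m = length(variables)) {
  stopifnot(is.data.frame(changes))
  fits <- lapply(variables, function(v) {
    adjusted_group_comparison(changes, paste0("pct_", v), group, covariates)
  })
  lv <- fits[[1]]$group_levels
  raw_p <- vapply(fits, `[[`, numeric(1), "raw_p")
  holm_p <- holm_adjust(setNames(raw_p, variables), m = m)
  out <- data.frame(variable = variables,
                    mean_1 = vapply(fits, function(f) f$adjusted_means[1],
                                    numeric(1)),
                    se_1 = vapply(fits, function(f) f$adjusted_se[1],
                                  numeric(1)),
                    mean_2 = vapply(fits, function(f) f$adjusted_means[2],
                                    numeric(1)),
                    se_2 = vapply(fits, function(f) f$adjusted_se[2],
                                  numeric(1)),
                    raw_p = raw_p, holm_p = unname(holm_p))
  names(out)[2:5] <- c(paste0("mean_", lv[1]), paste0("se_", lv[1]),
                       paste0("mean_", lv[2]), paste0("se_", lv[2]))
  attr(out, "group_levels") <- lv
  attr(out, "covariates") <- fits[[1]]$covariates
  attr(out, "n") <- fits[[1]]$n
  class(out) <- c("trab_comparison", class(out))
  out
}

#' @export
print.trab_comparison <- function(x, ...) {
  lv <- attr(x, "group_levels")
  cat(sprintf("Adjusted percent changes (%s n=%d vs %s n=%d; covariates: %s)\n",
              lv[1], attr(x, "n")[1], lv[2], attr(x, "n")[2],
              if (length(attr(x, "covariates")))
                paste(attr(x, "covariates"), collapse = ", ") else "none"))
  cat(sprintf("  %-16s %14s %14s %8s %8s\n", "variable",
              lv[1], lv[2], "p", "Holm p"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s %7.1f (%4.1f) %7.1f (%4.1f) %8.3f %8.3f\n",
                x$variable[i], x[[2]][i], x[[3]][i], x[[4]][i], x[[5]][i],
                x$raw_p[i], x$holm_p[i]))
  invisible(x)
}
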
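# Two-visit change and short-term precision statistics.

.profile_values <- function(x) {
  vars <- trab_variables()
  if (inherits(x, "microarch_profile")) x <- unclass(x)
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  missing_vars <- setdiff(vars, names(x))
  if (length(missing_vars))
    stop("profile is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  x[vars]
}

#' Absolute change between visits
#'
#' Elementwise follow-up minus baseline over the nine profile variables.
#'
#' @param baseline,followup [build_profile()] results (or named vectors with
#'   the nine variables).
#' @return Named numeric of absolute changes, in follow-up units.
#' @export
absolute_change <- function(baseline, followup) {
  b <- .profile_values(baseline)
  f <- .profile_values(followup)
  f - b
}

#' Percent change between visits
#'
#' 100 x absolute change / baseline, per variable. Variables with a zero
#' baseline are returned as `NA` with a warning (flagged, never silently
#' dropped).
#'
#' @param absolute Named numeric from [absolute_change()].
#' @param baseline The baseline profile.
#' @return Named numeric of percent changes.
#' @export
percent_change <- function(absolute, baseline) {
  b <- .profile_values(baseline)
  a <- absolute[names(b)]
  if (anyNA(a)) stop("absolute change is missing variable(s): ",
                     paste(names(b)[is.na(a)], collapse = ", "))
  zero <- b == 0
  if (any(zero))
    warning("percent change undefined for zero-baseline variable(s): ",
            paste(names(b)[zero], collapse = ", "))
  out <- 100 * a / b
  out[zero] <- NA_real_
  out
}

#' Per-subject change record
#'
#' @param subject_id Subject label.
#' @param baseline,followup Profiles for the two visits.
#' @param months_between_visits Interval in months.
#' @return One-row data frame with `abs_<var>` and `pct_<var>` columns.
#' @export
change_record <- function(subject_id, baseline, followup,
                          months_between_visits = NA_real_) {
  a <- absolute_change(baseline, followup)
  p <- percent_change(a, baseline)
  out <- data.frame(subject_id = subject_id,
                    months_between_visits = months_between_visits)
  for (v in names(a)) out[[paste0("abs_", v)]] <- a[[v]]
  for (v in names(p)) out[[paste0("pct_", v)]] <- p[[v]]
  out
}

#' Short-term precision: RMSCV% and ICC
#'
#' For each variable, the root-mean-square coefficient of variation across
#' subjects, RMSCV% = 100 x sqrt(mean over subjects of (SD_i / mean_i)^2),
#' and the one-way random-effects intraclass correlation (single
#' measurement): ICC = (MSB - MSW) / (MSB + (k0 - 1) MSW) with k0 the
#' (balanced-design) replicate count per subject. Negative ICC estimates are
#' reported and flagged, not truncated.
#'
#' @param replicates Data frame with a `subject_id` column and one column per
#'   variable; multiple rows per subject are replicate measurements.
#' @param variables Variables to summarize (default: all numeric columns).
#' @return Data frame of class `precision_report`: `variable`, `rmscv_pct`,
#'   `icc`, `icc_negative` flag.
#' @export
precision <- function(replicates, variables = NULL) {
  stopifnot(is.data.frame(replicates), "subject_id" %in% names(replicates))
  if (is.null(variables))
    variables <- setdiff(names(replicates)[vapply(replicates, is.numeric,
                                                  logical(1))], "subject_id")
  sid <- factor(replicates$subject_id)
  tab <- table(sid)
  if (length(tab) < 2) stop("precision requires at least 2 subjects")
  if (any(tab < 2)) stop("precision requires at least 2 replicates per subject")
  out <- lapply(variables, function(v) {
    y <- replicates[[v]]
    mu <- tapply(y, sid, mean)
    s <- tapply(y, sid, sd)
    if (any(mu == 0))
      stop("subject with zero mean for variable '", v,
           "': CV undefined")
    rmscv <- 100 * sqrt(mean((s / mu)^2))
    fit <- aov(y ~ sid)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    n <- length(y); i <- length(tab)
    k0 <- (n - sum(tab^2) / n) / (i - 1)
    icc <- (msb - msw) / (msb + (k0 - 1) * msw)
    data.frame(variable = v, rmscv_pct = rmscv, icc = icc,
               icc_negative = icc < 0)
  })
  out <- do.call(rbind, out)
  class(out) <- c("precision_report", class(out))
  out
}

#' @export
print.precision_report <- function(x, ...) {
  cat("Short-term precision (RMSCV%, one-way random-effects ICC)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s RMSCV %5.2f%%  ICC %.3f%s\n", x$variable[i],
                x$rmscv_pct[i], x$icc[i],
                if (x$icc_negative[i]) "  [negative: flagged]" else ""))
  invisible(x)
}
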
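#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns a tidy curve plus the median
#' survival, defined as the smallest time with survival at or below 0.5;
#' when the curve never reaches 0.5 the median is flagged "not reached"
#' (never encoded as infinity).
#'
#' @param times Follow-up times in months (non-negative).
#' @param events Event indicators, 0 = censored, 1 = event.
#' @return Object of class `km_curve`: tibble `time`, `n_risk`, `n_event`,
#'   `survival` (prepended with time 0, survival 1), with attributes
#'   `median` (numeric or `NA`) and `median_reached` (logical).
#' @examples
#' km_estimate(c(5, 10, 15), c(1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(
    time = c(0, fit$time),
    n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event),
    survival = c(1, fit$surv)
  )
  reached <- any(out$survival <= 0.5)
  med <- if (reached) min(out$time[out$survival <= 0.5]) else NA_real_
  attr(out, "median") <- med
  attr(out, "median_reached") <- reached
  class(out) <- c("km_curve", class(out))
  out
}

#' @export
print.km_curve <- function(x, ...) {
  med <- attr(x, "median")
  cat("Kaplan-Meier curve;", if (attr(x, "median_reached"))
    paste("median", med, "months") else "median not reached", "\n")
  NextMethod()
}

#' Median survival of a Kaplan-Meier curve
#' @param curve A `km_curve`.
#' @return Tibble `median` (NA when not reached), `median_reached`.
#' @export
km_median <- function(curve) {
  tibble(median = attr(curve, "median"),
         median_reached = attr(curve, "median_reached"))
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' (via [survival::survdiff()]), chi-square reference on groups - 1 degrees
#' of freedom.
#'
#' @param data Tibble with columns `time`, `event`, `group` (2 or more
#'   non-empty groups, at least one event overall).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data) {
  stopifnot(all(c("time", "event", "group") %in% names(data)))
  if (length(unique(data$group)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(data$event) == 0) stop("no events", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  df <- length(sd_$n) - 1
  tibble(statistic = sd_$chisq, df = df,
         p_value = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via [survival::coxph()] with Breslow tie
#' handling by default (Efron available). Reports per-term log-hazard
#' estimates, hazard ratios with Wald 95% intervals, and an honest
#' convergence flag; suspected separation (diverging estimates) is flagged,
#' not silently reported.
#'
#' @param times,events Survival outcome (months, 0/1).
#' @param covariates Data frame of covariates (no constant columns).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_result`: tibble `term`, `estimate`, `hr`,
#'   `conf_low`, `conf_high`, `p_value`, with attributes `converged` and
#'   `ties`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0) stop("need at least one covariate", call. = FALSE)
  if (sum(events) == 0) stop("no events", call. = FALSE)
  const <- vapply(covariates, function(v) length(unique(v)) == 1, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "),
         call. = FALSE)
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  separated <- any(abs(est) > 15 | se > 100, na.rm = TRUE)
  converged <- !separated && !anyNA(est)
  if (separated) {
    warning("possible separation: estimate diverging; fit flagged unconverged",
            call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    hr = exp(unname(est)),
    conf_low = exp(unname(est) - z * se),
    conf_high = exp(unname(est) + z * se),
    p_value = unname(sm$coefficients[, "Pr(>|z|)"])
  )
  attr(out, "converged") <- converged
  attr(out, "ties") <- ties
  class(out) <- c("cox_result", class(out))
  out
}

#' @export
glance.cox_result <- function(x, ...) {
  tibble(converged = attr(x, "converged"), ties = attr(x, "ties"),
         n_terms = nrow(x))
}

#' Stage-stratified survival report for signature classes
#'
#' Per stratum (default: tumor stage): Kaplan-Meier medians per class and a
#' log-rank test; strata below `min_n` samples are reported as
#' "insufficient n". Additionally fits a pooled stage-adjusted Cox model
#' with the signature class as exposure and stage dummy-coded against its
#' first observed level.
#'
#' @param classes Tibble `sample_id`, `class` (e.g. from
#'   [classify_weights()]), or with `quartile` when `grouping = "quartile"`.
#' @param annotations Annotation tibble with survival columns and the
#'   stratification variable.
#' @param strata Annotation column to stratify on (default `"stage"`).
#' @param endpoint `"dfs"` or `"os"`.
#' @param grouping `"class"` or `"quartile"`.
#' @param min_n Minimum stratum size analyzed (default 5).
#' @return List of class `stratified_report`: `per_stratum` tibble
#'   (`stratum`, `n`, `analyzed`, `statistic`, `df`, `p_value`, and one
#'   `median_<group>` column per group), `pooled` (the pooled log-rank
#'   tibble), and `adjusted_cox` (a [cox_fit()] result, or NULL when the
#'   strata variable is single-valued).
#' @export
stratified_report <- function(classes, annotations, strata = "stage",
                              endpoint = c("dfs", "os"),
                              grouping = c("class", "quartile"),
                              min_n = 5) {
  endpoint <- match.arg(endpoint)
  grouping <- match.arg(grouping)
  if (!grouping %in% names(classes)) {
    stop("grouping column '", grouping, "' not in `classes`", call. = FALSE)
  }
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  dat <- dplyr::inner_join(
    dplyr::select(classes, "sample_id", group = dplyr::all_of(grouping)),
    dplyr::select(annotations, "sample_id",
                  time = dplyr::all_of(tcol), event = dplyr::all_of(ecol),
                  stratum = dplyr::all_of(strata)),
    by = "sample_id")
  dat <- dat[complete.cases(dat[, c("time", "event")]), ]
  if (nrow(dat) == 0) stop("no samples with survival data", call. = FALSE)
  dat$stratum <- as.character(dat$stratum)
  groups <- sort(unique(dat$group))

  one_stratum <- function(d, name) {
    n <- nrow(d)
    base <- tibble(stratum = name, n = n)
    analyzable <- n >= min_n && length(unique(d$group)) >= 2 && sum(d$event) > 0
    meds <- lapply(groups, function(g) {
      dd <- d[d$group == g, ]
      if (nrow(dd) == 0) return(NA_real_)
      attr(km_estimate(dd$time, dd$event), "median")
    })
    names(meds) <- paste0("median_", gsub("[^A-Za-z0-9]+", "_", groups))
    if (analyzable) {
      lr <- logrank_test(d)
      dplyr::bind_cols(base, tibble(analyzed = TRUE, statistic = lr$statistic,
                                    df = lr$df, p_value = lr$p_value),
                       as_tibble(meds))
    } else {
      dplyr::bind_cols(base, tibble(analyzed = FALSE, statistic = NA_real_,
                                    df = NA_integer_, p_value = NA_real_),
                       as_tibble(meds))
    }
  }
  strata_levels <- sort(unique(dat$stratum))
  per_stratum <- dplyr::bind_rows(
    lapply(strata_levels, function(s) one_stratum(dat[dat$stratum == s, ], s)))
  if (!any(per_stratum$analyzed)) {
    stop("no stratum meets the minimum size", call. = FALSE)
  }
  pooled <- logrank_test(dat)
  adjusted <- NULL
  covs <- data.frame(group = factor(dat$group))
  if (length(strata_levels) > 1) {
    covs$stratum <- factor(dat$stratum)   # dummy-coded against first level
  }
  ok <- vapply(covs, function(v) length(unique(v)) > 1, logical(1))
  adjusted <- tryCatch(cox_fit(dat$time, dat$event, covs[, ok, drop = FALSE]),
                       error = function(e) NULL)
  structure(list(per_stratum = per_stratum, pooled = pooled,
                 adjusted_cox = adjusted, endpoint = endpoint,
                 grouping = grouping),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("Stratified survival report (", x$endpoint, " by ", x$grouping, ")\n",
      sep = "")
  print(x$per_stratum)
  cat("\nPooled log-rank: chisq =", signif(x$pooled$statistic, 4),
      "p =", signif(x$pooled$p_value, 3), "\n")
  if (!is.null(x$adjusted_cox)) {
    cat("\nStage-adjusted Cox:\n")
    print(x$adjusted_cox)
  }
  invisible(x)
}
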
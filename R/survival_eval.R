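#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator of the survival function; samples
#' censored exactly at an event time are counted at risk for that time.
#'
#' @param survival Data frame with `time` and `event` (plus anything else,
#'   ignored).
#' @return An object of class `km_curve`: data frame with `time`
#'   (ascending unique follow-up times), `n_risk`, `n_event`, `n_censor`
#'   and `survival`.
#' @export
km_estimate <- function(survival) {
  stopifnot(is.data.frame(survival),
            all(c("time", "event") %in% colnames(survival)))
  if (nrow(survival) == 0L) stop("empty survival input")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, survival = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time point(s), %d event(s)\n",
              nrow(x), sum(x$n_event)))
  print.data.frame(head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' K-group log-rank test
#'
#' Observed-minus-expected log-rank statistic across `k` groups, referred
#' to a chi-square distribution with `k - 1` degrees of freedom; with two
#' groups this is the classical log-rank test.
#'
#' @param survival Data frame with `time` and `event`.
#' @param group Vector of group labels, one per row of `survival`; every
#'   level must be non-empty.
#' @return List with `chi_square`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(survival, group) {
  stopifnot(is.data.frame(survival),
            all(c("time", "event") %in% colnames(survival)),
            length(group) == nrow(survival))
  group <- as.factor(group)
  tab <- table(group)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab == 0L)) stop("empty group(s): ",
                           paste(names(tab)[tab == 0L], collapse = ", "))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = survival$time,
                                             event = survival$event,
                                             g = group))
  df <- length(tab) - 1L
  list(chi_square = unname(sd$chisq), df = df,
       p_value = pchisq(unname(sd$chisq), df = df, lower.tail = FALSE),
       n_groups = length(tab))
}

# Left-continuous KM of the censoring distribution evaluated at t (G(t-)):
# product over censoring times strictly below t.
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                          data = data.frame(time = time, event = event))
  tt <- sf$time; ss <- sf$surv
  function(t, left = TRUE) {
    vapply(t, function(ti) {
      idx <- if (left) which(tt < ti) else which(tt <= ti)
      if (length(idx) == 0L) 1 else ss[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent ROC AUC for a risk score
#'
#' Cumulative-case / dynamic-control AUC at each horizon, with
#' inverse-probability-of-censoring weights (IPCW) from the Kaplan-Meier
#' estimate of the censoring distribution. Cases at horizon `t` are
#' samples with an observed event at or before `t` (weighted by
#' `1 / G(T-)`); controls are samples still under observation beyond `t`.
#' Score ties contribute 1/2. With no censoring the estimator reduces to
#' the plain concordance fraction between cases and controls. Horizons
#' with no observed case (or no control) give `NA`, not 0.5. As a rank
#' statistic, the AUC is invariant to strictly increasing transforms of
#' the score.
#'
#' @param scores Numeric risk scores, one per sample (higher = riskier).
#' @param survival Data frame with `time`, `event` aligned with `scores`.
#' @param horizons Evaluation horizons in years (default 1, 3, 5).
#' @param year_days Days per year used to convert horizons to the time
#'   unit of `survival` (default 365.25; set to 1 if `time` is already in
#'   the horizon unit).
#' @return An object of class `td_auc`: data frame with `horizon`,
#'   `horizon_time`, `auc`, `n_cases`, `n_controls`.
#' @export
td_auc <- function(scores, survival, horizons = c(1, 3, 5),
                   year_days = 365.25) {
  stopifnot(is.numeric(scores), is.data.frame(survival),
            all(c("time", "event") %in% colnames(survival)),
            length(scores) == nrow(survival))
  time <- survival$time; event <- survival$event
  ht <- horizons * year_days
  if (any(ht >= max(time))) {
    stop("every horizon must lie strictly before the maximum follow-up time")
  }
  G <- censoring_km(time, event)
  res <- lapply(seq_along(ht), function(k) {
    t0 <- ht[k]
    case <- which(time <= t0 & event == 1)
    ctrl <- which(time > t0)
    if (length(case) == 0L || length(ctrl) == 0L) {
      return(data.frame(horizon = horizons[k], horizon_time = t0,
                        auc = NA_real_, n_cases = length(case),
                        n_controls = length(ctrl)))
    }
    w <- 1 / G(time[case])
    bad <- !is.finite(w)
    if (any(bad)) {
      warning("case(s) with zero censoring-survival weight excluded")
      case <- case[!bad]; w <- w[!bad]
    }
    cmp <- outer(scores[case], scores[ctrl],
                 function(a, b) (a > b) + 0.5 * (a == b))
    auc <- sum(w * rowSums(cmp)) / (sum(w) * length(ctrl))
    data.frame(horizon = horizons[k], horizon_time = t0, auc = auc,
               n_cases = length(case), n_controls = length(ctrl))
  })
  out <- do.call(rbind, res)
  class(out) <- c("td_auc", "data.frame")
  out
}

#' @export
print.td_auc <- function(x, ...) {
  cat("Time-dependent AUC (IPCW, cumulative cases / dynamic controls)\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
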
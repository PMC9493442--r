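## Outcome statistics for index-derived groups: Kaplan-Meier curves,
## log-rank tests, univariate Cox proportional hazards (Efron ties), and
## the early/late relapse grouping by progression-free interval.

DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR <- 365.25

#' Kaplan-Meier fit per group
#'
#' Product-limit estimator with Greenwood variance, one curve per group;
#' censored times do not step the curve.
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 event indicators.
#' @param groups group labels (a single group if omitted).
#' @return named list of data.frames (`time`, `nRisk`, `nEvent`, `survival`,
#'   `stdErr`), one per group, plus the underlying `survival::survfit`
#'   object as attribute `fit`.
#' @export
kmFit <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit, censored = FALSE)
  lev <- levels(droplevels(groups))
  strata <- if (is.null(sm$strata)) rep(lev[1], length(sm$time))
            else sub("^groups=", "", as.character(sm$strata))
  out <- lapply(lev, function(s) {
    i <- strata == s
    data.frame(time = sm$time[i], nRisk = sm$n.risk[i], nEvent = sm$n.event[i],
               survival = sm$surv[i], stdErr = sm$std.err[i])
  })
  names(out) <- lev
  attr(out, "fit") <- fit
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic over the shared
#' event times, 1 degree of freedom.
#'
#' @param times,events as in [kmFit()].
#' @param groups labels with exactly 2 levels.
#' @return list: `chisq`, `df`, `p`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("log-rank test needs exactly 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chisq = unname(sd$chisq), df = 1,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional hazards
#'
#' Partial-likelihood fit with Efron handling of tied event times. Monotone
#' likelihood / non-convergence is flagged rather than silently reported.
#'
#' @param times,events as in [kmFit()].
#' @param covariate numeric per-sample covariate.
#' @param minEvents minimum number of events.
#' @param ties tie-handling method.
#' @return list: `beta` (log hazard ratio), `se`, `z`, `p`, `hr`, `ciLower`,
#'   `ciUpper`, `converged`.
#' @export
coxUnivariate <- function(times, events, covariate, minEvents = 10,
                          ties = "efron") {
  if (sum(events) < minEvents)
    stop("need >= ", minEvents, " events (got ", sum(events), ")")
  if (stats::sd(covariate) == 0) stop("constant covariate carries no information")
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ covariate,
                        ties = ties))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  sm <- summary(fit)
  beta <- unname(stats::coef(fit))
  se <- sm$coefficients[1, "se(coef)"]
  list(beta = beta, se = se, z = beta / se,
       p = sm$coefficients[1, "Pr(>|z|)"],
       hr = exp(beta), ciLower = exp(beta - 1.96 * se),
       ciUpper = exp(beta + 1.96 * se),
       converged = is.null(attr(fit, "flagged")),
       flag = attr(fit, "flagged"))
}

#' Early vs late relapse groups from the progression-free interval
#'
#' GBM: early relapse is a progression event before 6 months (< 182.64
#' days), late relapse a PFI beyond 12 months (> 365.25 days); samples
#' between the windows are excluded. LGG: a single 5-year cutoff (1826.25
#' days) separates early (event before it) from late (PFI beyond it).
#' "Early" requires an observed progression event; "late" admits samples
#' censored beyond the cutoff, since their interval already exceeds it.
#'
#' @param clinical data.frame with `sample_id`, `pfi_time` (days),
#'   `pfi_event`.
#' @param cohortKind `"GBM"` or `"LGG"`.
#' @return named character vector of `"early"`/`"late"` labels over the
#'   samples that fall in either window.
#' @export
relapseGroups <- function(clinical, cohortKind = c("GBM", "LGG")) {
  cohortKind <- match.arg(cohortKind)
  need <- c("sample_id", "pfi_time", "pfi_event")
  if (!all(need %in% colnames(clinical)))
    stop("clinical table must provide ", paste(need, collapse = ", "))
  t <- clinical$pfi_time
  e <- clinical$pfi_event
  if (cohortKind == "GBM") {
    earlyCut <- 6 * DAYS_PER_MONTH
    lateCut <- 12 * DAYS_PER_MONTH
  } else {
    earlyCut <- lateCut <- 5 * DAYS_PER_YEAR
  }
  early <- t < earlyCut & e == 1
  late <- t > lateCut
  lab <- ifelse(early, "early", ifelse(late, "late", NA_character_))
  stats::setNames(lab, clinical$sample_id)[!is.na(lab)]
}
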
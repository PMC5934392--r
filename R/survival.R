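#' Kaplan-Meier estimate with survival-at-time queries
#'
#' Product-limit estimator per group via [survival::survfit()], plus
#' evaluation of the step function at requested times (e.g. the 3-year
#' recurrence-free survival rate). Queries beyond a group's last observed
#' time return the last step value and are flagged.
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 event indicators.
#' @param groups optional group labels (one curve per group).
#' @param at optional numeric times at which to evaluate the curves.
#' @return list with `fit` (the `survfit` object), `curves` (data.frame:
#'   `group`, `time`, `n_risk`, `n_event`, `surv`) and, when `at` is given,
#'   `at` (data.frame: `group`, `time`, `surv`, `extrapolated`).
#' @export
km_estimate <- function(times, events, groups = NULL, at = NULL) {
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("`events` must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  df <- data.frame(time = times, event = events, group = as.character(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(df$group), length(s$time)) else {
    sub("^group=", "", as.character(s$strata))
  }
  curves <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                       n_event = s$n.event, surv = s$surv,
                       stringsAsFactors = FALSE)
  out <- list(fit = fit, curves = curves)
  if (!is.null(at)) {
    rows <- lapply(unique(curves$group), function(g) {
      cg <- curves[curves$group == g, ]
      last_t <- max(df$time[df$group == g])
      sf <- stats::stepfun(cg$time, c(1, cg$surv), right = FALSE)
      data.frame(group = g, time = at, surv = sf(at),
                 extrapolated = at > last_t, stringsAsFactors = FALSE)
    })
    out$at <- do.call(rbind, rows)
  }
  out
}

#' Log-rank test between survival curves
#'
#' Observed-minus-expected chi-square statistic over the pooled event times
#' ([survival::survdiff()], rho = 0), df = groups - 1.
#'
#' @inheritParams km_estimate
#' @return list with `chi2`, `df`, `p`, `n_events`. With zero events the test
#'   is undefined: `chi2 = 0`, `p = 1`, `degenerate = TRUE`.
#' @export
logrank_test <- function(times, events, groups) {
  if (any(times < 0)) stop("negative survival times")
  if (length(unique(groups)) < 2) stop("log-rank needs >= 2 groups")
  if (sum(events) == 0) {
    return(list(chi2 = 0, df = length(unique(groups)) - 1L, p = 1,
                n_events = 0L, degenerate = TRUE))
  }
  df_ <- data.frame(time = times, event = events, group = as.character(groups))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df_,
                            rho = 0)
  k <- length(sd_$n)
  list(chi2 = unname(sd_$chisq), df = k - 1L,
       p = stats::pchisq(sd_$chisq, k - 1L, lower.tail = FALSE),
       n_events = sum(events), degenerate = FALSE)
}

#' Cox proportional-hazards fit with likelihood-ratio inference
#'
#' Thin wrapper over [survival::coxph()] that standardizes the outputs the
#' pipeline reports: hazard ratios with Wald 95% CIs on the log-hazard scale
#' and the likelihood-ratio test against the null model as the headline p.
#'
#' @param clinical clinical data.frame (columns `os_time`/`os_event` or
#'   `rfs_time`/`rfs_event` plus the covariates).
#' @param covariates character vector of covariate column names.
#' @param endpoint `"RFS"` (default) or `"OS"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: `table` (data.frame: `term`, `coef`,
#'   `hr`, `ci_low`, `ci_high`, `wald_p`), `lrt_stat`, `lrt_df`, `lrt_p`,
#'   `loglik`, `n`, `n_events`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(clinical, covariates, endpoint = c("RFS", "OS"),
                    ties = c("efron", "breslow")) {
  endpoint <- match.arg(endpoint)
  ties <- match.arg(ties)
  tcol <- if (endpoint == "RFS") "rfs_time" else "os_time"
  ecol <- if (endpoint == "RFS") "rfs_event" else "os_event"
  need <- c(tcol, ecol, covariates)
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  const <- covariates[vapply(clinical[covariates],
                             function(v) length(unique(v)) < 2, logical(1))]
  if (length(const)) stop("constant covariate(s): ", paste(const, collapse = ", "))
  if (sum(clinical[[ecol]]) < length(covariates) + 1) {
    stop("too few events for the number of covariates")
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", tcol, ", ", ecol, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = clinical, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    wald_p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(table = tab,
                 lrt_stat = lrt,
                 lrt_df = sum(!is.na(stats::coef(fit))),
                 lrt_p = stats::pchisq(lrt, sum(!is.na(stats::coef(fit))),
                                       lower.tail = FALSE),
                 loglik = fit$loglik[2],
                 n = sm$n, n_events = sm$nevent,
                 endpoint = endpoint, ties = ties, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s, %s ties): n=%d, events=%d, LRT p=%.3g\n",
              x$endpoint, x$ties, x$n, x$n_events, x$lrt_p))
  print(x$table, digits = 3)
  invisible(x)
}

#' Restrict to the adjuvant-chemotherapy analysis subset
#'
#' Keeps patients with AJCC stage II, III or IV disease and no distant
#' metastasis — the subset in which adjuvant chemotherapy benefit is
#' assessed.
#'
#' @param clinical clinical data.frame with `stage` and `distant_metastasis`.
#' @return the filtered data.frame.
#' @export
subset_for_adjuvant_analysis <- function(clinical) {
  need <- c("stage", "distant_metastasis")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks column(s): ",
                         paste(miss, collapse = ", "))
  clinical[clinical$stage %in% c("II", "III", "IV") &
             clinical$distant_metastasis == 0, , drop = FALSE]
}

#' Subtype-by-chemotherapy interaction analysis
#'
#' Fits a Cox model of recurrence-free survival on subtype, chemotherapy,
#' their product term, and the sex/age/stage adjustment covariates; the
#' interaction p-value is the likelihood-ratio test of the product term
#' (full vs additive model). Also reports the within-subtype chemotherapy
#' hazard ratios from stratified fits of chemo alone, matching the
#' per-subtype Kaplan-Meier analysis.
#'
#' @param clinical clinical data.frame (the adjuvant subset is the intended
#'   input; apply [subset_for_adjuvant_analysis()] first).
#' @param labels `subtype_labels` or named MP/EP vector covering
#'   `clinical$sample_id`.
#' @param stage_coding `"numeric"` (default: ordered 1-4) or `"factor"`.
#' @param adjust character vector of adjustment covariates (default
#'   sex, age, stage).
#' @return list: `interaction_p`, `interaction_coef` (log-HR of the product
#'   term), `full_fit`, `reduced_fit` (both `cox_fit`), and `stratified`
#'   (data.frame per subtype: chemo `hr`, `ci_low`, `ci_high`, `lrt_p`, `n`).
#' @export
interaction_test <- function(clinical, labels, stage_coding = c("numeric", "factor"),
                             adjust = c("sex", "age", "stage")) {
  stage_coding <- match.arg(stage_coding)
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  cl <- clinical[clinical$sample_id %in% names(lab), , drop = FALSE]
  cl$subtype_mp <- as.integer(lab[cl$sample_id] == "MP")
  for (st in c("MP", "EP")) {
    for (arm in 0:1) {
      if (!any(cl$subtype_mp == (st == "MP") & cl$chemo == arm)) {
        stop(sprintf("empty stratum: subtype %s, chemo = %d", st, arm))
      }
    }
  }
  cl$sex_m <- as.integer(cl$sex == "M")
  cl$stage_num <- match(cl$stage, c("I", "II", "III", "IV"))
  stage_cov <- if (stage_coding == "numeric") "stage_num" else "stage"
  adj <- adjust
  adj[adj == "sex"] <- "sex_m"
  adj[adj == "stage"] <- stage_cov
  adj <- adj[vapply(cl[adj], function(v) length(unique(v)) > 1, logical(1))]
  cl$subtype_x_chemo <- cl$subtype_mp * cl$chemo
  full <- cox_fit(cl, c("subtype_mp", "chemo", "subtype_x_chemo", adj),
                  endpoint = "RFS")
  reduced <- cox_fit(cl, c("subtype_mp", "chemo", adj), endpoint = "RFS")
  lrt <- 2 * (full$loglik - reduced$loglik)
  strat <- do.call(rbind, lapply(c("EP", "MP"), function(st) {
    sub <- cl[cl$subtype_mp == (st == "MP"), , drop = FALSE]
    f <- cox_fit(sub, "chemo", endpoint = "RFS")
    data.frame(subtype = st, hr = f$table$hr, ci_low = f$table$ci_low,
               ci_high = f$table$ci_high, lrt_p = f$lrt_p, n = f$n,
               stringsAsFactors = FALSE)
  }))
  list(interaction_p = stats::pchisq(lrt, 1, lower.tail = FALSE),
       interaction_stat = lrt,
       interaction_coef = full$table$coef[full$table$term == "subtype_x_chemo"],
       full_fit = full, reduced_fit = reduced, stratified = strat)
}

#' Per-stage log-rank comparison of MP vs EP survival
#'
#' @param clinical clinical data.frame with `stage` and RFS columns.
#' @param labels MP/EP labels over `clinical$sample_id`.
#' @param endpoint `"RFS"` (default) or `"OS"`.
#' @return data.frame, one row per stage: `stage`, `n`, `chi2`, `p`,
#'   `skipped` (TRUE when a stage holds one subtype only).
#' @export
km_by_stage <- function(clinical, labels, endpoint = c("RFS", "OS")) {
  endpoint <- match.arg(endpoint)
  tcol <- if (endpoint == "RFS") "rfs_time" else "os_time"
  ecol <- if (endpoint == "RFS") "rfs_event" else "os_event"
  lab <- if (inherits(labels, "subtype_labels")) labels$label else labels
  cl <- clinical[clinical$sample_id %in% names(lab), , drop = FALSE]
  cl$subtype <- lab[cl$sample_id]
  out <- lapply(sort(unique(cl$stage)), function(st) {
    sub <- cl[cl$stage == st, , drop = FALSE]
    if (length(unique(sub$subtype)) < 2) {
      return(data.frame(stage = st, n = nrow(sub), chi2 = NA_real_,
                        p = NA_real_, skipped = TRUE))
    }
    lr <- logrank_test(sub[[tcol]], sub[[ecol]], sub$subtype)
    data.frame(stage = st, n = nrow(sub), chi2 = lr$chi2, p = lr$p,
               skipped = FALSE)
  })
  do.call(rbind, out)
}
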
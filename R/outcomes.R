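#' 20-2-20 clinical risk staging
#'
#' Counts the strict-inequality risk factors M-protein > 2 g/dL, involved/
#' uninvolved FLC ratio > 20 and bone-marrow plasma cells > 20%; none is
#' low risk, one intermediate, two or three high. Boundary values (exactly
#' 2, 20, 20) do not count. Patients with any factor missing get an NA
#' stage.
#'
#' @param m_protein baseline M-protein, g/dL.
#' @param flc_ratio involved/uninvolved free light-chain ratio.
#' @param bmpc_percent bone-marrow plasma-cell percentage (0-100).
#' @return data.frame: `factors` (0-3) and `stage`
#'   (factor low/intermediate/high); NA where inputs are missing.
#' @export
stage_20_2_20 <- function(m_protein, flc_ratio, bmpc_percent) {
  if (any(c(m_protein, flc_ratio, bmpc_percent) < 0, na.rm = TRUE)) {
    stop("staging inputs must be non-negative")
  }
  factors <- (m_protein > 2) + (flc_ratio > 20) + (bmpc_percent > 20)
  stage <- factor(ifelse(factors == 0, "low",
                         ifelse(factors == 1, "intermediate", "high")),
                  levels = c("low", "intermediate", "high"))
  data.frame(factors = factors, stage = stage)
}

#' Evolving M-protein and hemoglobin detection
#'
#' eMP: some M-protein measurement within 12 months of diagnosis rises at
#' least 25% over baseline AND by at least 0.5 g/dL in absolute terms.
#' eHb: some hemoglobin measurement within 12 months falls at least
#' 0.5 g/dL below baseline. Measurements at exactly 12 months count. The
#' baseline is the month-0 value of each series; with a zero M-protein
#' baseline the relative rule is vacuous and only the absolute minimum is
#' applied (with a warning).
#'
#' @param mp_series,hb_series data.frames with columns `month` and `value`
#'   (or `NULL` to skip that flag). Month offsets must be strictly
#'   increasing and include 0.
#' @return list: `emp`, `ehb` (logical; NA for a skipped series).
#' @export
detect_evolving_biomarkers <- function(mp_series = NULL, hb_series = NULL) {
  eval_series <- function(s, what) {
    if (is.null(s) || nrow(s) == 0L) return(NULL)
    s <- s[order(s$month), , drop = FALSE]
    if (any(duplicated(s$month))) stop(what, ": duplicate month offsets")
    if (s$month[1L] != 0) stop(what, ": baseline (month 0) measurement required")
    s
  }
  mp <- eval_series(mp_series, "mp_series")
  hb <- eval_series(hb_series, "hb_series")
  emp <- NA
  if (!is.null(mp)) {
    base <- mp$value[1L]
    win <- mp$value[mp$month > 0 & mp$month <= 12]
    if (base == 0 && length(win)) {
      warning("zero M-protein baseline: eMP evaluated on the absolute rule only")
      emp <- any(win - 0 >= 0.5)
    } else {
      emp <- any((win - base) / base >= 0.25 & win - base >= 0.5)
    }
  }
  ehb <- NA
  if (!is.null(hb)) {
    base <- hb$value[1L]
    win <- hb$value[hb$month > 0 & hb$month <= 12]
    ehb <- any(base - win >= 0.5)
  }
  list(emp = emp, ehb = ehb)
}

#' Evolving-biomarker flags for a whole cohort
#'
#' Applies [detect_evolving_biomarkers()] to each patient's `mp` and `hb`
#' series in a long-format table (see [read_biomarker_series()]).
#'
#' @param series data.frame: patient_id, marker ("mp"/"hb"), month, value.
#' @return data.frame: patient_id, emp, ehb.
#' @export
detect_evolving_cohort <- function(series) {
  pids <- unique(series$patient_id)
  res <- lapply(pids, function(p) {
    s <- series[series$patient_id == p, , drop = FALSE]
    take <- function(m) {
      d <- s[s$marker == m, c("month", "value"), drop = FALSE]
      if (nrow(d)) d else NULL
    }
    fl <- detect_evolving_biomarkers(take("mp"), take("hb"))
    data.frame(patient_id = p, emp = fl$emp, ehb = fl$ehb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Kaplan-Meier fit with Greenwood confidence intervals
#'
#' Product-limit estimator per group (or overall), 95% confidence intervals
#' from Greenwood's variance, group medians (smallest time with survival
#' <= 0.5; NA when the curve never reaches 0.5), and the median follow-up
#' by the reverse Kaplan-Meier method (event indicators flipped).
#'
#' @param times positive event/censoring times.
#' @param events logical (or 0/1) progression indicators.
#' @param groups optional group labels.
#' @return object of class `km_fit`: `curves` (group, time, n_risk,
#'   survival, lower, upper), `medians` (group, median, lower, upper),
#'   `median_followup`, and the underlying `survfit` object.
#' @export
km_fit <- function(times, events, groups = NULL) {
  if (any(times <= 0)) stop("times must be positive")
  events <- as.logical(events)
  df <- data.frame(times = times, events = events,
                   g = if (is.null(groups)) factor(rep("all", length(times)))
                       else factor(groups))
  fit <- survival::survfit(survival::Surv(times, events) ~ g, data = df,
                           conf.type = "log")
  smry <- summary(fit)
  grp <- if (is.null(smry$strata)) rep(levels(df$g), length(smry$time))
         else sub("^g=", "", as.character(smry$strata))
  curves <- data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
                       survival = smry$surv, lower = smry$lower,
                       upper = smry$upper, stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- t(as.matrix(tab))
  medians <- data.frame(
    group = sub("^g=", "", rownames(tab) %||% levels(df$g)),
    median = unname(tab[, "median"]),
    lower = unname(tab[, "0.95LCL"]), upper = unname(tab[, "0.95UCL"]),
    stringsAsFactors = FALSE)
  rev_fit <- survival::survfit(survival::Surv(times, !events) ~ 1)
  rev_tab <- summary(rev_fit)$table
  structure(list(curves = curves, medians = medians,
                 median_followup = unname(rev_tab["median"]),
                 survfit = fit),
            class = "km_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit\n")
  print(x$medians, row.names = FALSE)
  cat(sprintf("median follow-up (reverse KM): %s\n",
              format(x$median_followup)))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  graphics::plot(x$survfit, col = seq_len(nrow(x$medians)),
                 xlab = "time", ylab = "survival", ...)
  graphics::legend("topright", legend = x$medians$group,
                   col = seq_len(nrow(x$medians)), lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank test for differences between survival curves
#'
#' @param times positive times.
#' @param events logical progression indicators.
#' @param groups group labels; at least 2 non-empty groups.
#' @return list: `chisq`, `df` (groups - 1), `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ groups)
  df <- nlevels(groups) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling. Covariates may
#' mix numeric columns and factors (e.g. genetic risk group plus clinical
#' stage); each coefficient is reported as a hazard ratio with Wald 95% CI
#' and p-value.
#'
#' @param covariates data.frame of covariates (no constant columns).
#' @param times positive times.
#' @param events logical progression indicators.
#' @return object of class `cox_fit`: `table` (term, HR, CI, p),
#'   `loglik` (null, fitted), `concordance`, `n_events`, and the `coxph`
#'   model object.
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2L,
                  logical(1))
  if (any(const)) {
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  }
  events <- as.logical(events)
  dat <- cbind(covariates,
               .time = times, .event = events)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (sum(events) < length(stats::coef(fit))) {
    stop("fewer events than parameters")
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik,
                 concordance = unname(s$concordance["C"]),
                 n_events = sum(events), model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (Efron ties), %d events, concordance %.3f\n",
              x$n_events, x$concordance))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' `LR = 2 (loglik_extended - loglik_base)` on the difference in parameter
#' count, plus both models' Harrell C. The models must be fit to the same
#' patients and the base covariates must be a subset of the extended ones.
#'
#' @param base,extended [cox_fit()] objects.
#' @return list: `lr_chisq`, `df`, `p`, `c_base`, `c_extended`, `delta_c`.
#' @export
compare_cox_models <- function(base, extended) {
  stopifnot(inherits(base, "cox_fit"), inherits(extended, "cox_fit"))
  if (base$model$n != extended$model$n) {
    stop("models were fit to different numbers of patients")
  }
  tb <- base$model$assign; te <- extended$model$assign
  if (!all(names(tb) %in% names(te))) {
    stop("models are not nested: base covariates must be a subset")
  }
  df <- length(stats::coef(extended$model)) - length(stats::coef(base$model))
  if (df < 0) stop("extended model has fewer parameters than base")
  lr <- 2 * (extended$loglik[2L] - base$loglik[2L])
  list(lr_chisq = lr, df = df,
       p = if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE),
       c_base = base$concordance, c_extended = extended$concordance,
       delta_c = extended$concordance - base$concordance)
}

#' Harrell's concordance index for censored survival data
#'
#' Fraction of usable patient pairs (orderable under censoring) in which
#' the higher risk score belongs to the patient who progresses earlier;
#' tied scores contribute 0.5. The 95% confidence interval is a normal
#' (Noether-type) approximation on the concordance standard error.
#'
#' @param risk_scores finite numeric scores (higher = higher risk).
#' @param times positive times.
#' @param events logical progression indicators.
#' @return list: `c`, `se`, `ci_low`, `ci_high`, `n_pairs` (usable pairs).
#' @export
c_index <- function(risk_scores, times, events) {
  if (any(!is.finite(risk_scores))) stop("risk scores must be finite")
  events <- as.logical(events)
  cc <- survival::concordance(survival::Surv(times, events) ~ risk_scores,
                              reverse = TRUE)
  counts <- cc$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no usable (orderable) pairs")
  se <- sqrt(cc$var)
  z <- stats::qnorm(0.975)
  list(c = unname(cc$concordance), se = unname(se),
       ci_low = unname(cc$concordance - z * se),
       ci_high = unname(cc$concordance + z * se),
       n_pairs = unname(usable))
}

#' Association between evolving biomarkers and the high-risk genetic group
#'
#' Cross-product odds ratio of an evolving flag for high-risk versus other
#' patients from the 2x2 table (Haldane-Anscombe 0.5 correction on zero
#' cells), with a two-sided Fisher exact p and a normal-approximation 95%
#' CI on the log odds ratio. Alternatively a logistic regression
#' (`flag ~ high_risk`) odds ratio with Wald CI.
#'
#' @param flags logical evolving indicators (eMP or eHb).
#' @param risk_groups risk-group labels; `"high"` versus everything else.
#' @param method `"table"` (default) or `"logistic"`.
#' @return list: `odds_ratio`, `ci_low`, `ci_high`, `p`, `table` (2x2).
#' @export
biomarker_association <- function(flags, risk_groups,
                                  method = c("table", "logistic")) {
  method <- match.arg(method)
  flags <- as.logical(flags)
  high <- risk_groups == "high"
  if (!any(high) || all(high)) stop("both risk groups must be non-empty")
  if (all(flags) || !any(flags)) {
    stop("degenerate flags: all TRUE or all FALSE")
  }
  a <- sum(high & flags); b <- sum(high & !flags)
  c_ <- sum(!high & flags); d <- sum(!high & !flags)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("high", "other"), c("evolving", "stable")))
  if (method == "table") {
    aa <- c(a, b, c_, d)
    if (any(aa == 0)) aa <- aa + 0.5
    or <- (aa[1] * aa[4]) / (aa[2] * aa[3])
    se <- sqrt(sum(1 / aa))
    z <- stats::qnorm(0.975)
    p <- stats::fisher.test(tab)$p.value
    list(odds_ratio = or, ci_low = exp(log(or) - z * se),
         ci_high = exp(log(or) + z * se), p = p, table = tab)
  } else {
    fit <- stats::glm(flags ~ high, family = stats::binomial())
    co <- summary(fit)$coefficients["highTRUE", ]
    z <- stats::qnorm(0.975)
    list(odds_ratio = unname(exp(co["Estimate"])),
         ci_low = unname(exp(co["Estimate"] - z * co["Std. Error"])),
         ci_high = unname(exp(co["Estimate"] + z * co["Std. Error"])),
         p = unname(co["Pr(>|z|)"]), table = tab)
  }
}
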
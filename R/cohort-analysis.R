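#' Compare a feature between two patient subgroups
#'
#' Two-sample comparison of an imaging feature (e.g. the AUC-CSH indices)
#' between the two levels of a grouping variable. A Student t-test is used
#' when both groups pass a Shapiro-Wilk normality screen at alpha = 0.05;
#' otherwise a Mann-Whitney rank-sum test. P-values are two-tailed and
#' reported raw (no multiplicity correction is applied anywhere in this
#' pipeline).
#'
#' @param cohort a cohort data.frame (see [generate_cohort()]).
#' @param group name of a two-level grouping column (binary or
#'   two-level factor/character), e.g. `"bmi"`, `"mycn"`, `"event"`,
#'   `"cog_high"`.
#' @param feature name of the numeric feature column, e.g.
#'   `"auccsh_total"`.
#' @return A one-row data.frame with per-group n/mean/sd, the test used,
#'   and the p-value.
#' @export
subgroup_compare <- function(cohort, group, feature) {
  g <- cohort[[group]]
  x <- cohort[[feature]]
  if (is.null(g) || is.null(x)) stop("unknown column: ", group, " or ", feature)
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping `", group, "` must have exactly 2 levels")
  x1 <- x[g == lev[1]]; x2 <- x[g == lev[2]]
  if (length(x1) < 2 || length(x2) < 2)
    stop("each group needs >= 2 members (got ", length(x1), " and ",
         length(x2), ")")
  normal <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > 0.05
  }
  use_t <- normal(x1) && normal(x2)
  p <- if (stats::sd(c(x1, x2)) == 0) {
    1  # identical values in both groups: no evidence of difference
  } else if (use_t) {
    stats::t.test(x1, x2)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))$p.value
  }
  data.frame(feature = feature, group = group,
             level1 = as.character(lev[1]), n1 = length(x1),
             mean1 = mean(x1), sd1 = stats::sd(x1),
             level2 = as.character(lev[2]), n2 = length(x2),
             mean2 = mean(x2), sd2 = stats::sd(x2),
             test = if (stats::sd(c(x1, x2)) == 0) "degenerate"
                    else if (use_t) "t" else "rank-sum",
             p = p, stringsAsFactors = FALSE)
}

cox_fit_rows <- function(cohort, variables, stage) {
  fml <- stats::as.formula(paste(
    "survival::Surv(followup_months, event) ~",
    paste(variables, collapse = " + ")))
  diag_notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = cohort, ties = "breslow"),
    warning = function(w) {
      diag_notes <<- c(diag_notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  res <- data.frame(
    variable = rownames(co), stage = stage,
    hr = co[, "exp(coef)"],
    ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
    p = co[, "Pr(>|z|)"],
    diagnostic = if (length(diag_notes)) paste(unique(diag_notes),
                                               collapse = "; ") else "",
    stringsAsFactors = FALSE, row.names = NULL)
  list(fit = fit, table = res)
}

#' Univariate Cox regression for event-free survival
#'
#' Partial-likelihood fit of a single covariate against
#' `Surv(followup_months, event)`, with the Breslow approximation for ties.
#' Monotone-likelihood / infinite-coefficient warnings are captured into
#' the `diagnostic` column rather than raised.
#'
#' @param cohort a cohort data.frame with `followup_months` and `event`.
#' @param variable covariate column name (numeric or binary).
#' @return A data.frame with `variable`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `diagnostic`.
#' @export
univariate_cox <- function(cohort, variable) {
  if (sum(cohort$event) < 1) stop("need at least one event")
  v <- cohort[[variable]]
  if (is.null(v)) stop("unknown column: ", variable)
  if (length(unique(v)) < 2) stop("constant covariate: ", variable)
  cox_fit_rows(cohort, variable, stage = "univariate")$table
}

#' Backward-stepwise multivariate Cox regression
#'
#' Fits all candidates jointly, then iteratively removes the variable with
#' the largest Wald p-value above `p_remove`, refitting after each removal,
#' until every retained variable has p <= `p_remove`. The default removal
#' threshold of 0.10 is the common backward-Wald convention. `p_remove = 1`
#' retains all candidates, `p_remove = 0` eliminates all.
#'
#' @param cohort a cohort data.frame.
#' @param candidates character vector of covariate columns (typically
#'   those with univariate p < 0.05).
#' @param p_remove Wald-p removal threshold (default 0.10).
#' @return A list: `final` (data.frame of the retained model, possibly
#'   zero rows), `retained` (character), `steps` (data.frame log of each
#'   elimination), `history` (list of per-stage coefficient tables).
#' @export
multivariate_cox_backward <- function(cohort, candidates, p_remove = 0.10) {
  if (length(candidates) < 1) stop("need at least one candidate variable")
  if (sum(cohort$event) < 1) stop("need at least one event")
  for (v in candidates) {
    if (is.null(cohort[[v]])) stop("unknown column: ", v)
    if (length(unique(cohort[[v]])) < 2) stop("constant covariate: ", v)
  }
  vars <- candidates
  steps <- data.frame(step = integer(0), removed = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  history <- list()
  k <- 0
  repeat {
    if (length(vars) == 0) break
    fit <- cox_fit_rows(cohort, vars, stage = "multivariate")
    history[[length(history) + 1]] <- fit$table
    worst <- which.max(fit$table$p)
    if (fit$table$p[worst] <= p_remove) break
    k <- k + 1
    steps <- rbind(steps, data.frame(step = k,
                                     removed = fit$table$variable[worst],
                                     p = fit$table$p[worst],
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, fit$table$variable[worst])
  }
  final <- if (length(vars)) history[[length(history)]] else
    data.frame(variable = character(0), stage = character(0), hr = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
               diagnostic = character(0), stringsAsFactors = FALSE)
  list(final = final, retained = vars, steps = steps, history = history)
}

#' Optimal ROC cutoff by the Youden index
#'
#' Scans the observed feature values as candidate cutoffs and returns the
#' one maximising Youden's J = sensitivity + specificity - 1. `direction`
#' fixes which side of the cutoff predicts an event: `"lower"` means
#' values <= cutoff are called positive (appropriate for the AUC-CSH
#' index, where lower values mean more heterogeneity and worse outcome);
#' `"auto"` picks the direction with the larger maximal J. J is piecewise
#' constant between observed values, so the maximiser is an interval; the
#' returned cutoff is the midpoint of that tie region, which for a
#' perfectly separating feature is the midpoint of the gap between the
#' two classes.
#'
#' @param cohort a cohort data.frame.
#' @param feature numeric feature column (default `"auccsh_total"`).
#' @param outcome binary outcome column (default `"event"`).
#' @param direction `"lower"`, `"higher"`, or `"auto"`.
#' @return A list: `cutoff`, `youden_j`, `direction`, `sensitivity`,
#'   `specificity`.
#' @export
roc_optimal_cutoff <- function(cohort, feature = "auccsh_total",
                               outcome = "event",
                               direction = c("lower", "higher", "auto")) {
  direction <- match.arg(direction)
  x <- cohort[[feature]]
  y <- cohort[[outcome]]
  if (is.null(x) || is.null(y)) stop("unknown column: ", feature, " or ", outcome)
  if (length(unique(y)) != 2)
    stop("degenerate outcome: both classes must be present")
  y <- as.integer(y == max(y))
  scan <- function(dir) {
    cs <- sort(unique(x))
    J <- vapply(cs, function(cc) {
      pos <- if (dir == "lower") x <= cc else x >= cc
      mean(pos[y == 1]) + mean(!pos[y == 0]) - 1
    }, numeric(1))
    m <- max(J)
    idx <- which(J == m)
    # midpoint of the tie region: J stays at its max from the first
    # achieving value up to (exclusive) the value following the last one
    lo <- cs[min(idx)]
    hi <- if (dir == "lower") {
      if (max(idx) < length(cs)) cs[max(idx) + 1] else cs[max(idx)]
    } else {
      if (min(idx) > 1) cs[min(idx) - 1] else cs[min(idx)]
    }
    list(cutoff = (lo + hi) / 2, j = m, dir = dir)
  }
  best <- switch(direction,
    lower = scan("lower"),
    higher = scan("higher"),
    auto = {
      a <- scan("lower"); b <- scan("higher")
      if (b$j > a$j) b else a
    })
  pos <- if (best$dir == "lower") x <= best$cutoff else x >= best$cutoff
  list(cutoff = best$cutoff, youden_j = best$j, direction = best$dir,
       sensitivity = mean(pos[y == 1]), specificity = mean(!pos[y == 0]))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates per group with a k-group log-rank test. When no
#' events occur at all the log-rank statistic is undefined; this is
#' reported (`p = NA` with a note), not raised.
#'
#' @param cohort a cohort data.frame.
#' @param group grouping column name (factor/character/binary) or a vector
#'   of group labels of length `nrow(cohort)`.
#' @return A list: `fit` (a [survival::survfit] object), `chisq`, `df`,
#'   `p`, `n_groups`, `note`.
#' @export
km_logrank <- function(cohort, group) {
  g <- if (length(group) == 1 && is.character(group)) cohort[[group]] else group
  if (is.null(g) || length(g) != nrow(cohort))
    stop("grouping must name a column or give one label per patient")
  if (any(table(g) == 0)) stop("every group must be non-empty")
  d <- data.frame(time = cohort$followup_months, status = cohort$event,
                  group = factor(g))
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d)
  if (sum(d$status) == 0 || nlevels(d$group) < 2) {
    note <- if (nlevels(d$group) < 2) "single group: log-rank not applicable"
            else "all observations censored: log-rank undefined"
    return(list(fit = fit, chisq = NA_real_,
                df = max(nlevels(d$group) - 1L, 0L),
                p = NA_real_, n_groups = nlevels(d$group), note = note))
  }
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ group, data = d,
                            rho = 0)
  df <- length(sd_$n) - 1
  list(fit = fit, chisq = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       n_groups = length(sd_$n), note = "")
}

#' Combined AUC-CSH / bone-marrow-involvement risk stratification
#'
#' Three-group rule on the total-lesion heterogeneity index and
#' bone-marrow involvement (BMI): Group I has AUC-CSH above the cutoff and
#' no BMI (neither risk factor), Group II exactly one of
#' {AUC-CSH <= cutoff, BMI}, Group III both. The groups partition the
#' cohort.
#'
#' @param cohort a cohort data.frame with `auccsh_total` and `bmi`.
#' @param cutoff AUC-CSH dichotomisation point (default 0.49).
#' @return A factor with levels `"I"`, `"II"`, `"III"`, one per patient.
#' @export
stratify_risk_groups <- function(cohort, cutoff = 0.49) {
  low_auc <- cohort$auccsh_total <= cutoff
  bmi <- cohort$bmi == 1
  n_risk <- low_auc + bmi
  factor(c("I", "II", "III")[n_risk + 1], levels = c("I", "II", "III"))
}

#' Baseline characteristics table with between-event-group tests
#'
#' Continuous variables are summarised as mean +/- sd when both event
#' groups pass a Shapiro-Wilk screen, otherwise median (IQR), and compared
#' by the Mann-Whitney rank-sum test. Categorical variables are summarised
#' as n (%) per level and compared by the chi-square test. Constant
#' columns are flagged as degenerate with `p = NA`.
#'
#' @param cohort a cohort data.frame with an `event` column.
#' @param continuous character vector of continuous columns.
#' @param categorical character vector of categorical columns.
#' @return A data.frame, one row per variable (or per categorical level),
#'   with summaries for the whole cohort and both event groups plus the
#'   comparison p-value.
#' @export
baseline_table <- function(cohort,
                           continuous = c("age"),
                           categorical = c("sex", "tumour_site", "inss_stage",
                                           "cog_risk")) {
  if (nrow(cohort) == 0) stop("empty cohort")
  ev <- cohort$event == 1
  fmt_cont <- function(v, sub = rep(TRUE, length(v))) {
    v <- v[sub]
    norm_ok <- length(v) >= 3 && stats::sd(v) > 0 &&
      stats::shapiro.test(v)$p.value > 0.05
    if (norm_ok) sprintf("%.3f±%.3f", mean(v), stats::sd(v))
    else sprintf("%.2f (%.2f, %.2f)", stats::median(v),
                 stats::quantile(v, .25), stats::quantile(v, .75))
  }
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    if (is.null(x)) stop("unknown column: ", v)
    degen <- stats::sd(x) == 0
    p <- if (degen) NA_real_ else
      suppressWarnings(stats::wilcox.test(x[ev], x[!ev], exact = FALSE))$p.value
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "", type = "continuous",
      total = fmt_cont(x), without_event = fmt_cont(x, !ev),
      with_event = fmt_cont(x, ev), p = p,
      note = if (degen) "degenerate: constant column" else "",
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- cohort[[v]]
    if (is.null(x)) stop("unknown column: ", v)
    tab <- table(x, factor(ev, levels = c(FALSE, TRUE)))
    degen <- nrow(tab) < 2
    p <- if (degen) NA_real_ else
      suppressWarnings(stats::chisq.test(tab))$p.value
    for (lv in rownames(tab)) {
      n_tot <- sum(x == lv)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lv, type = "categorical",
        total = sprintf("%d (%.1f%%)", n_tot, 100 * n_tot / nrow(cohort)),
        without_event = sprintf("%d (%.1f%%)", tab[lv, 1],
                                100 * tab[lv, 1] / max(sum(!ev), 1)),
        with_event = sprintf("%d (%.1f%%)", tab[lv, 2],
                             100 * tab[lv, 2] / max(sum(ev), 1)),
        p = p, note = if (degen) "degenerate: single level" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
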
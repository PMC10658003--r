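# Group-comparison layer: evidence grading on the logarithmic Jeffreys
# scheme, BIC-approximate Bayes factors for the two-factor (task x group)
# repeated-measures design, and a rank-based JZS Bayes factor for
# distribution-free two-group comparisons. All Bayes factors are reported on
# the natural-log scale.

.evidence_thresholds <- c(anecdotal = 0, moderate = 1.1, strong = 2.3,
                          very_strong = 3.4, decisive = 4.6)

#' Grade a log Bayes factor on the Jeffreys scheme
#'
#' Thresholds on `|log BF|`: anecdotal below 1.1, moderate from 1.1, strong
#' from 2.3, very strong from 3.4, decisive from 4.6 (= ln 100 to one
#' decimal). The sign gives the direction: positive is evidence for,
#' negative against; zero is graded anecdotal-for by the closed lower bound.
#'
#' @param log_bf Finite natural-log Bayes factor.
#' @return An `evidence_grade`: list with `log_bf`, `label` and `direction`.
#' @export
grade_evidence <- function(log_bf) {
  if (!is.numeric(log_bf) || length(log_bf) != 1L || !is.finite(log_bf))
    stop("log_bf must be a single finite number", call. = FALSE)
  a <- abs(log_bf)
  labs <- names(.evidence_thresholds)
  label <- labs[findInterval(a, .evidence_thresholds)]
  structure(list(log_bf = log_bf, label = label,
                 direction = if (log_bf >= 0) "for" else "against"),
            class = "evidence_grade")
}

#' @export
print.evidence_grade <- function(x, ...) {
  cat(sprintf("log(BF) = %.3f: %s evidence %s\n", x$log_bf,
              gsub("_", " ", x$label), x$direction))
  invisible(x)
}

#' BIC-approximate Bayes factors for the task x group design
#'
#' Fits the candidate set of mixed models for one within factor (task) and
#' one between factor (group) with a subject random intercept — null, +task,
#' +group, +task+group, full — by maximum likelihood (lme4) and converts BIC
#' differences into approximate log Bayes factors against the null,
#' `log BF = (BIC_null - BIC_model) / 2`. Inclusion Bayes factors per effect
#' compare the summed (BIC-approximate) marginal likelihoods of the matched
#' models with and without the effect; the interaction is compared against
#' the two-main-effects model. The output is BIC-approximate, not a
#' default-prior Bayes factor.
#'
#' @param data Data frame.
#' @param response,subject,task,group Column names (strings).
#' @return A `mixed_anova_bf`: list with `log_bf` (per model, vs null),
#'   `log_bf_incl` (per effect: `task`, `group`, `interaction`), `bic`,
#'   and `approximation = "BIC"`.
#' @export
mixed_anova_bf <- function(data, response, subject, task, group) {
  d <- data.frame(y = data[[response]], id = factor(data[[subject]]),
                  task = factor(data[[task]]), group = factor(data[[group]]))
  if (anyNA(d)) stop("design error: missing values", call. = FALSE)
  if (nlevels(d$task) != 2L)
    stop("design error: task must have exactly two levels", call. = FALSE)
  if (nlevels(d$group) != 2L)
    stop("design error: group must have exactly two levels", call. = FALSE)
  tab <- table(d$id, d$task)
  if (any(tab == 0L))
    stop("design error: every subject needs both task levels", call. = FALSE)
  gtab <- table(d$id, d$group)
  if (any(rowSums(gtab > 0) != 1L))
    stop("design error: group must be constant within subject", call. = FALSE)
  if (any(table(unique(d[, c("id", "group")])$group) < 3L))
    stop("design error: need at least 3 subjects per group", call. = FALSE)
  forms <- list(
    null = y ~ 1 + (1 | id),
    task = y ~ task + (1 | id),
    group = y ~ group + (1 | id),
    task_group = y ~ task + group + (1 | id),
    full = y ~ task * group + (1 | id))
  fits <- lapply(forms, function(f)
    suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))))
  bic <- vapply(fits, stats::BIC, numeric(1))
  log_bf <- (bic[["null"]] - bic) / 2
  # matched-model inclusion: ratio of summed approximate marginal likelihoods
  logml <- -bic / 2
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  incl <- c(
    task = lse(logml[c("task", "task_group")]) -
      lse(logml[c("null", "group")]),
    group = lse(logml[c("group", "task_group")]) -
      lse(logml[c("null", "task")]),
    interaction = logml[["full"]] - logml[["task_group"]])
  structure(list(log_bf = log_bf[-1L], log_bf_incl = incl, bic = bic,
                 approximation = "BIC"), class = "mixed_anova_bf")
}

#' @export
print.mixed_anova_bf <- function(x, ...) {
  cat("BIC-approximate log Bayes factors vs the null model:\n")
  print(round(x$log_bf, 3))
  cat("Inclusion log BF per effect (matched models):\n")
  print(round(x$log_bf_incl, 3))
  invisible(x)
}

#' Rank-based JZS Bayes factor for two independent groups
#'
#' A distribution-free stand-in for a Bayesian Mann-Whitney comparison: the
#' pooled values are rank-transformed and a two-sample JZS Bayes factor
#' (Cauchy prior scale `r`) is computed on the ranks. Rank-approximate, not a
#' sampling-based Bayes factor.
#'
#' @param values_a,values_b Numeric samples (n >= 3 each).
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @return Natural-log BF10.
#' @export
rank_group_bf <- function(values_a, values_b, r = sqrt(2) / 2) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 3L || n2 < 3L)
    stop("need at least 3 values per group", call. = FALSE)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L)
    stop("undefined: all values tied", call. = FALSE)
  rk <- rank(pooled)
  a <- rk[seq_len(n1)]; b <- rk[n1 + seq_len(n2)]
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("undefined: zero rank variance within groups",
                     call. = FALSE)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  jzs_logbf_t(t, n_eff = n1 * n2 / (n1 + n2), df = n1 + n2 - 2, r = r)
}
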
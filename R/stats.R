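#' Recognition score
#'
#' Proportion of hits minus proportion of false alarms for one
#' encoding condition: `hits/n_old - false_alarms/n_new`. Ranges over
#' \[-1, 1\]; 1 is perfect memory, 0 is chance.
#'
#' @param hits,n_old hit count and number of old (studied) items.
#' @param false_alarms,n_new false-alarm count and number of new items.
#' @return scalar recognition score.
#' @examples
#' recognition_score(35, 70, 0, 30)   # 0.5
#' recognition_score(35, 70, 15, 30)  # 0 (chance)
#' @export
recognition_score <- function(hits, n_old, false_alarms, n_new) {
  stopifnot(n_old > 0, n_new > 0, hits >= 0, false_alarms >= 0,
            hits <= n_old, false_alarms <= n_new)
  hits / n_old - false_alarms / n_new
}

#' Self-referential memory bias score
#'
#' Recognition score of the self condition minus that of the other
#' condition; positive values indicate a self-referential memory
#' advantage.
#'
#' @param rec_self,rec_other recognition scores.
#' @return scalar SRM bias.
#' @examples
#' srm_bias(0.49, 0.35)  # 0.14, the control-group regime
#' @export
srm_bias <- function(rec_self, rec_other) {
  stopifnot(is.finite(rec_self), is.finite(rec_other))
  rec_self - rec_other
}

#' Score a behavioral record
#'
#' Adds `hit_rate`, `fa_rate` and `recognition` per condition to a
#' [gen_behavior]-style table and computes each subject's SRM bias.
#'
#' @param record a `"behavioral_record"` data.frame (may hold several
#'   subjects).
#' @return list with `per_condition` (the augmented table) and
#'   `per_subject` (subject_id, group, srm_bias).
#' @export
score_behavior <- function(record) {
  stopifnot(is.data.frame(record),
            all(c("subject_id", "group", "condition", "hits",
                  "false_alarms", "n_old", "n_new") %in% names(record)))
  record$hit_rate <- record$hits / record$n_old
  record$fa_rate <- record$false_alarms / record$n_new
  record$recognition <- mapply(recognition_score, record$hits,
                               record$n_old, record$false_alarms,
                               record$n_new)
  per_subject <- do.call(rbind, lapply(split(record, record$subject_id),
    function(df) {
      data.frame(subject_id = df$subject_id[1L], group = df$group[1L],
                 srm_bias = srm_bias(
                   df$recognition[df$condition == "self"],
                   df$recognition[df$condition == "other"]))
    }))
  rownames(per_subject) <- NULL
  list(per_condition = record, per_subject = per_subject)
}

#' Mixed-design (split-plot) ANOVA
#'
#' Classical mixed-model sums of squares for a between-subjects group
#' factor crossed with a within-subjects condition factor (every
#' subject measured in all conditions), fit via
#' `aov(value ~ group * condition + Error(subject/condition))`.
#' No sphericity correction is applied. With zero error variance the
#' affected F is undefined and flagged.
#'
#' @param values numeric matrix, subject x condition (column names =
#'   condition labels).
#' @param group character/factor of per-subject group labels.
#' @return data.frame with rows `group`, `condition`,
#'   `group:condition`: `effect`, `df1`, `df2`, `F`, `p`, `flagged`.
#' @export
mixed_anova <- function(values, group) {
  stopifnot(is.matrix(values), nrow(values) == length(group),
            ncol(values) >= 2L)
  if (anyNA(values)) stop("missing cells: design must be balanced")
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) < 2L))
    stop("need >= 2 subjects in each of >= 2 groups")
  conds <- colnames(values)
  if (is.null(conds)) conds <- paste0("c", seq_len(ncol(values)))
  n <- nrow(values)
  long <- data.frame(
    value = as.vector(values),
    subject = factor(rep(seq_len(n), times = ncol(values))),
    condition = factor(rep(conds, each = n), levels = conds),
    group = rep(group, times = ncol(values)))
  fit <- stats::aov(value ~ group * condition + Error(subject/condition),
                    data = long)
  s <- summary(fit)
  btw <- as.data.frame(s[["Error: subject"]][[1L]])
  wth <- as.data.frame(s[["Error: subject:condition"]][[1L]])
  scale <- mean(long$value^2) + .Machine$double.xmin
  pick <- function(tab, term) {
    r <- trimws(rownames(tab)) == term
    err <- trimws(rownames(tab)) == "Residuals"
    f <- tab[r, "F value"]; p <- tab[r, "Pr(>F)"]
    # zero error variance (relative to the data scale) makes F
    # meaningless even when rounding yields a finite ratio
    flag <- !is.finite(f) || tab[err, "Mean Sq"] < 1e-20 * scale
    data.frame(effect = term, df1 = tab[r, "Df"], df2 = tab[err, "Df"],
               F = f, p = p, flagged = flag)
  }
  out <- rbind(pick(btw, "group"),
               pick(wth, "condition"),
               pick(wth, "group:condition"))
  rownames(out) <- NULL
  out
}

#' Independent two-sample t-test (pooled variance)
#'
#' Two-tailed Student t with pooled variance, `df = n_a + n_b - 2`
#' (the convention matching reported df of 34 for 18 + 18 subjects).
#'
#' @param a,b numeric samples (each length >= 2).
#' @return one-row data.frame: `statistic`, `df`, `p`, `effect`
#'   (mean difference a - b).
#' @export
ttest_ind <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp <- ((length(a) - 1L) * stats::var(a) + (length(b) - 1L) * stats::var(b))
  if (sp == 0) stop("zero pooled variance: t undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  data.frame(statistic = unname(ht$statistic),
             df = unname(ht$parameter), p = ht$p.value,
             effect = mean(a) - mean(b))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors, `n >= 3`, non-constant.
#' @return one-row data.frame: `statistic` (r), `df`, `p`, `effect`
#'   (R^2 = r^2).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  data.frame(statistic = unname(ht$estimate),
             df = unname(ht$parameter), p = ht$p.value,
             effect = unname(ht$estimate)^2)
}

#' Simple linear regression y ~ x
#'
#' Least-squares slope/intercept with the overall F-test and
#' `R^2 = r^2` (identical to the squared Pearson correlation).
#'
#' @param x predictor (e.g. SRM bias score); @param y response.
#' @return one-row data.frame: `slope`, `intercept`, `statistic`
#'   (F), `df1`, `df2`, `p`, `r_squared`.
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0) stop("constant predictor: regression undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  f <- s$fstatistic
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             statistic = unname(f["value"]),
             df1 = unname(f["numdf"]), df2 = unname(f["dendf"]),
             p = unname(stats::pf(f["value"], f["numdf"], f["dendf"],
                                  lower.tail = FALSE)),
             r_squared = s$r.squared)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` with `m = length(pvals)` (or an explicit factor);
#' adjusted values never fall below the raw ones.
#'
#' @param pvals numeric p-values in \[0, 1\] (NA passed through).
#' @param m correction factor (default `length(pvals)`).
#' @return adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5, 0.04))
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  pmin(1, pvals * m)
}
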
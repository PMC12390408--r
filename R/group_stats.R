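GROUP_LABELS <- c("HC", "PDoff", "PDon", "NOFOGoff", "NOFOGon",
                  "FOGoff", "FOGon")

# the eight pairwise comparisons reported per parameter
COMPARISON_PAIRS <- list(c("HC", "PDoff"), c("HC", "PDon"),
                         c("HC", "NOFOGoff"), c("HC", "NOFOGon"),
                         c("HC", "FOGoff"), c("HC", "FOGon"),
                         c("NOFOGoff", "FOGoff"), c("NOFOGon", "FOGon"))

#' Construct a group sample
#'
#' One number per subject for one parameter in one group. Group labels are
#' drawn from the fixed study set: healthy controls (HC), pooled
#' parkinsonian patients OFF/ON medication (PDoff, PDon), and the
#' freezing-of-gait subgroups (NOFOGoff/on, FOGoff/on).
#'
#' @param group Group label.
#' @param parameter Parameter name (e.g. `"SL"`).
#' @param values Numeric vector, one value per subject.
#' @return An object of class `group_sample`.
#' @export
group_sample <- function(group, parameter, values) {
  group <- match.arg(group, GROUP_LABELS)
  values <- as.numeric(values)
  if (any(!is.finite(values))) fk_stop("non-finite values", "data")
  structure(list(group = group, parameter = parameter, values = values),
            class = "group_sample")
}

#' @export
print.group_sample <- function(x, ...) {
  cat(sprintf("<group_sample> %s / %s: n = %d, mean = %.3g, sd = %.3g\n",
              x$group, x$parameter, length(x$values), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' Normality gate for a parameter
#'
#' Shapiro-Wilk test at alpha = 0.05 on each group's values; a parameter
#' is classified `non_normal` if any group rejects normality. This
#' conservative pooling yields a single test choice per parameter: a
#' Mann-Whitney U test when non-normal, an independent-samples t test
#' otherwise.
#'
#' @param samples List of [group_sample()] objects for one parameter.
#' @param alpha Significance level of the gate.
#' @return `"normal"` or `"non_normal"` (character scalar), with the
#'   per-group Shapiro-Wilk p-values as attribute `p_values`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!length(samples)) fk_stop("no samples", "parameter")
  p <- vapply(samples, function(s) {
    stopifnot(inherits(s, "group_sample"))
    if (length(s$values) < 3L) {
      fk_stop(sprintf("group %s has fewer than 3 values", s$group), "gate")
    }
    if (stats::sd(s$values) == 0) {
      fk_stop(sprintf("group %s is degenerate (constant values)", s$group),
              "gate")
    }
    stats::shapiro.test(s$values)$p.value
  }, numeric(1L))
  names(p) <- vapply(samples, `[[`, "", "group")
  structure(if (any(p < alpha)) "non_normal" else "normal", p_values = p)
}

#' Two-group comparison gated by normality
#'
#' Two-sided Mann-Whitney U test (`non_normal` gate) or two-sided
#' independent-samples t test (`normal` gate). The Mann-Whitney test uses
#' the exact distribution for small samples without ties (n <= 20 per
#' group) and the normal approximation with tie correction otherwise; the
#' t test is Student's equal-variance test by default, with a Welch
#' option. No multiple-testing correction is applied: raw p-values are
#' reported per comparison.
#'
#' @param a,b [group_sample()] objects with the same parameter.
#' @param gate `"normal"` or `"non_normal"` from [normality_gate()].
#' @param welch Use Welch's unequal-variance t test instead of Student's.
#' @return An object of class `comparison_result`: list with `groups`,
#'   `parameter`, `test`, `p_value`, `stars` and per-group descriptives
#'   (mean, sd, median, IQR).
#' @export
compare_groups <- function(a, b, gate, welch = FALSE) {
  stopifnot(inherits(a, "group_sample"), inherits(b, "group_sample"))
  if (!identical(a$parameter, b$parameter)) {
    fk_stop(sprintf("parameter mismatch: %s vs %s", a$parameter,
                    b$parameter), "parameter")
  }
  gate <- match.arg(as.character(gate), c("normal", "non_normal"))
  if (gate == "non_normal") {
    exact <- length(a$values) <= 20L && length(b$values) <= 20L &&
      !any(duplicated(c(a$values, b$values)))
    ht <- suppressWarnings(stats::wilcox.test(a$values, b$values,
                                              alternative = "two.sided",
                                              exact = exact))
    test <- "mann_whitney_u"
  } else {
    ht <- stats::t.test(a$values, b$values, alternative = "two.sided",
                        var.equal = !welch)
    test <- "t_test"
  }
  p <- ht$p.value
  descr <- function(s) {
    c(n = length(s$values), mean = mean(s$values), sd = stats::sd(s$values),
      median = stats::median(s$values), iqr = stats::IQR(s$values))
  }
  structure(list(groups = c(a$group, b$group), parameter = a$parameter,
                 test = test, p_value = p, stars = p_stars(p),
                 descriptives = rbind(descr(a), descr(b))),
            class = "comparison_result")
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s vs %s, %s, p = %.4g %s\n",
              x$parameter, x$groups[1L], x$groups[2L], x$test, x$p_value,
              x$stars))
  invisible(x)
}

#' Run the full comparison grid
#'
#' For every parameter present, runs the eight study comparisons
#' (HC vs PDoff, HC vs PDon, HC vs NOFOGoff, HC vs NOFOGon, HC vs FOGoff,
#' HC vs FOGon, NOFOGoff vs FOGoff, NOFOGon vs FOGon), each first gated by
#' [normality_gate()] over all available groups for that parameter and
#' then tested with [compare_groups()]. Comparisons whose groups are
#' missing are skipped with a warning.
#'
#' @param samples List of [group_sample()] objects (several parameters
#'   allowed), or a data frame with columns `group`, `parameter`, `value`
#'   (one row per subject).
#' @param welch Passed to [compare_groups()].
#' @return Data frame with columns `parameter`, `group_a`, `group_b`,
#'   `test`, `p_value`, `stars`.
#' @export
run_comparison_grid <- function(samples, welch = FALSE) {
  if (is.data.frame(samples)) {
    need <- c("group", "parameter", "value")
    if (!all(need %in% names(samples))) {
      fk_stop("data frame needs columns group, parameter, value", "format")
    }
    samples <- lapply(split(samples, samples[, c("group", "parameter")],
                            drop = TRUE),
                      function(d) group_sample(as.character(d$group[1L]),
                                               as.character(d$parameter[1L]),
                                               d$value))
  }
  params <- unique(vapply(samples, `[[`, "", "parameter"))
  rows <- list()
  for (par in params) {
    sp <- Filter(function(s) s$parameter == par, samples)
    names(sp) <- vapply(sp, `[[`, "", "group")
    gate <- normality_gate(sp)
    for (pair in COMPARISON_PAIRS) {
      if (!all(pair %in% names(sp))) {
        fk_warn(sprintf("%s: missing group(s) %s; comparison skipped", par,
                        paste(setdiff(pair, names(sp)), collapse = ", ")))
        next
      }
      cr <- compare_groups(sp[[pair[1L]]], sp[[pair[2L]]], gate,
                           welch = welch)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = par, group_a = pair[1L], group_b = pair[2L],
                   test = cr$test, p_value = cr$p_value, stars = cr$stars)
    }
  }
  if (!length(rows)) {
    return(data.frame(parameter = character(0), group_a = character(0),
                      group_b = character(0), test = character(0),
                      p_value = numeric(0), stars = character(0)))
  }
  do.call(rbind, rows)
}

#' Pool the freezing subgroups into the overall patient groups
#'
#' The overall parkinsonian groups are the unions of the subgroups:
#' PDoff = NOFOGoff + FOGoff and PDon = NOFOGon + FOGon. Given a
#' subject-level table with the subgroup labels, appends the pooled rows.
#'
#' @param df Data frame with columns `group`, `parameter`, `value` (and
#'   optionally more, which are carried along).
#' @return The table with PDoff/PDon rows appended.
#' @export
pool_pd_groups <- function(df) {
  stopifnot(is.data.frame(df), "group" %in% names(df))
  off <- df[df$group %in% c("NOFOGoff", "FOGoff"), , drop = FALSE]
  on <- df[df$group %in% c("NOFOGon", "FOGon"), , drop = FALSE]
  if (nrow(off)) off$group <- "PDoff"
  if (nrow(on)) on$group <- "PDon"
  rbind(df, off, on)
}
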
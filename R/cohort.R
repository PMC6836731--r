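### Cohort-level analyses: peak extraction from stimulation time courses,
### group comparisons (from raw values or printed summary statistics), and
### deletion-burden versus age regression.

#' Peak of a stimulation time course
#'
#' The highest copies-per-cell value a subject reaches over the measured
#' days, with the day it occurred; ties are broken by the earliest day.
#' This is the per-subject statistic compared across age groups.
#'
#' @param x a [SubjectTimecourse()], or a numeric vector of values whose
#'   names are the measurement days.
#' @param ... unused.
#' @return List with `peak` (copies per cell equivalent) and `peakDay`.
#' @examples
#' tc <- SubjectTimecourse("s1", "young", 30,
#'                         days = c(0, 3, 6, 10),
#'                         values = c(400, 900, 1500, 1200))
#' extractPeak(tc)   # peak 1500 on day 6
#' @name extractPeak
NULL

#' @rdname extractPeak
setMethod("extractPeak", "SubjectTimecourse", function(x, ...) {
    i <- which.max(x@values)    # days are sorted: first max = earliest day
    list(peak = x@values[i], peakDay = x@days[i])
})

#' @rdname extractPeak
setMethod("extractPeak", "numeric", function(x, ...) {
    if (length(x) == 0)
        stop("empty series")
    days <- if (is.null(names(x))) seq_along(x) - 1L else as.integer(names(x))
    o <- order(days)
    x <- x[o]
    days <- days[o]
    i <- which.max(x)
    list(peak = unname(x[i]), peakDay = days[i])
})

## ---------------------------------------------------------------------------
## Pairwise group comparisons
## ---------------------------------------------------------------------------

## Welch (or pooled) two-sample t from group summaries; handles the
## zero-variance degenerate case explicitly.
.tFromSummary <- function(n1, m1, s1, n2, m2, s2, pooled = FALSE) {
    if (pooled) {
        df <- n1 + n2 - 2
        sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
        se2 <- sp2 * (1 / n1 + 1 / n2)
    } else {
        v1 <- s1^2 / n1
        v2 <- s2^2 / n2
        se2 <- v1 + v2
        df <- if (se2 > 0)
            se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
        else n1 + n2 - 2
    }
    d <- m1 - m2
    if (se2 == 0) {
        t <- if (d == 0) 0 else sign(d) * Inf
        p <- if (d == 0) 1 else 0
    } else {
        t <- d / sqrt(se2)
        p <- 2 * stats::pt(-abs(t), df)
    }
    list(diff = d, statistic = t, df = df, p.value = p)
}

## Tukey HSD p-values from group summaries via the studentized range.
.tukeyFromSummary <- function(n, m, s) {
    k <- length(n)
    dfw <- sum(n - 1)
    msw <- if (dfw > 0) sum((n - 1) * s^2) / dfw else 0
    pairs <- utils::combn(k, 2)
    res <- apply(pairs, 2, function(ij) {
        i <- ij[1]; j <- ij[2]
        d <- m[i] - m[j]
        se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
        if (se == 0) {
            q <- if (d == 0) 0 else Inf
            p <- if (d == 0) 1 else 0
        } else {
            q <- abs(d) / se
            p <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
        }
        c(diff = d, statistic = q, df = dfw, p.value = p)
    })
    data.frame(i = pairs[1, ], j = pairs[2, ], t(res))
}

#' Pairwise comparisons of group means
#'
#' Compares every pair of groups by unpaired two-tailed tests.  Input can be
#' raw values (`data.frame` with columns `group` and `value`) or printed
#' summary statistics (`data.frame` with columns `group`, `n`, `mean`,
#' `sd`), so published group summaries can be re-tested without raw data;
#' the two modes agree exactly when the summaries are computed from the raw
#' values.
#'
#' Procedures: `welch_t` (unequal-variance t, the robust default),
#' `pooled_t` (classical Student t), `anova_tukey` (one-way ANOVA F test
#' plus Tukey honest-significant-difference adjusted pairwise p-values from
#' the studentized-range distribution).
#'
#' @param x `data.frame` in raw or summary form (see above).
#' @param procedure `"welch_t"`, `"pooled_t"` or `"anova_tukey"`.
#' @return `data.frame` with one row per group pair: `group1`, `group2`,
#'   `diff` (mean1 - mean2), `statistic` (t, or studentized range q),
#'   `df` and `p.value`.  For `anova_tukey` the overall F statistic and its
#'   p-value are attached as attributes `F` and `F.p.value`.
#' @examples
#' peaks <- data.frame(group = c("old", "young"),
#'                     n = c(22, 22), mean = c(809, 1528), sd = c(332, 272))
#' compareGroups(peaks, "welch_t")
#' @export
compareGroups <- function(x, procedure = c("welch_t", "pooled_t",
                                           "anova_tukey")) {
    procedure <- match.arg(procedure)
    stopifnot(is.data.frame(x))
    if (all(c("group", "n", "mean", "sd") %in% names(x))) {
        summ <- x
    } else if (all(c("group", "value") %in% names(x))) {
        groups <- split(x$value, x$group)
        if (any(lengths(groups) < 2))
            stop("raw mode needs at least 2 values per group")
        summ <- data.frame(group = names(groups),
                           n = lengths(groups),
                           mean = vapply(groups, mean, numeric(1)),
                           sd = vapply(groups, stats::sd, numeric(1)))
    } else {
        stop("'x' must have columns group/value (raw) or group/n/mean/sd ",
             "(summary)")
    }
    if (nrow(summ) < 2)
        stop("at least 2 groups are required")
    if (any(summ$n < 2))
        stop("each group needs n >= 2")
    summ$group <- as.character(summ$group)
    if (procedure == "anova_tukey") {
        tk <- .tukeyFromSummary(summ$n, summ$mean, summ$sd)
        out <- data.frame(group1 = summ$group[tk$i], group2 = summ$group[tk$j],
                          diff = tk$diff, statistic = tk$statistic,
                          df = tk$df, p.value = tk$p.value)
        ## overall one-way ANOVA F from the same summaries
        N <- sum(summ$n)
        k <- nrow(summ)
        gm <- sum(summ$n * summ$mean) / N
        ssb <- sum(summ$n * (summ$mean - gm)^2)
        ssw <- sum((summ$n - 1) * summ$sd^2)
        Fst <- (ssb / (k - 1)) / (ssw / (N - k))
        attr(out, "F") <- Fst
        attr(out, "F.p.value") <- stats::pf(Fst, k - 1, N - k,
                                            lower.tail = FALSE)
        return(out)
    }
    pooled <- procedure == "pooled_t"
    pairs <- utils::combn(nrow(summ), 2)
    rows <- apply(pairs, 2, function(ij) {
        i <- ij[1]; j <- ij[2]
        r <- .tFromSummary(summ$n[i], summ$mean[i], summ$sd[i],
                           summ$n[j], summ$mean[j], summ$sd[j],
                           pooled = pooled)
        c(r$diff, r$statistic, r$df, r$p.value)
    })
    data.frame(group1 = summ$group[pairs[1, ]],
               group2 = summ$group[pairs[2, ]],
               diff = rows[1, ], statistic = rows[2, ], df = rows[3, ],
               p.value = rows[4, ])
}

#' Deletion burden versus age regression
#'
#' Ordinary least squares of the percent of mtDNA molecules carrying the
#' common deletion on age, optionally restricted to a subset of group
#' labels — the design used to ask whether deletion burden rises with age
#' and whether healthy centenarians escape the trend.
#'
#' @param records `data.frame` with columns `age` and `deletionPct`, and
#'   optionally `group`.
#' @param groups optional character vector of group labels to keep.
#' @return List with `slope` (percent per year), `intercept`, `r2`,
#'   `p.value` (two-tailed on the slope), `n` and the fitted `lm` object.
#' @examples
#' rec <- data.frame(age = c(30, 50, 70, 90), deletionPct = c(1, 2, 3, 4))
#' deletionVsAge(rec)$r2   # collinear: 1
#' @export
deletionVsAge <- function(records, groups = NULL) {
    stopifnot(is.data.frame(records),
              all(c("age", "deletionPct") %in% names(records)))
    if (!is.null(groups)) {
        if (!"group" %in% names(records))
            stop("'records' has no 'group' column to subset on")
        records <- records[records$group %in% groups, , drop = FALSE]
    }
    if (nrow(records) < 3)
        stop("at least 3 records are required")
    if (stats::var(records$age) == 0)
        stop("age is constant; the regression is degenerate")
    fit <- stats::lm(deletionPct ~ age, data = records)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = sm$r.squared,
         p.value = sm$coefficients["age", "Pr(>|t|)"],
         n = nrow(records),
         fit = fit)
}

#' Cohort peaks as a data frame
#'
#' Applies [extractPeak()] to a list of time courses and assembles the
#' per-subject peak table used for group comparisons.
#'
#' @param timecourses list of [SubjectTimecourse()].
#' @return `data.frame` with `subjectId`, `group`, `age`, `peak`,
#'   `peakDay`.
#' @export
cohortPeaks <- function(timecourses) {
    stopifnot(length(timecourses) >= 1,
              all(vapply(timecourses, is, logical(1), "SubjectTimecourse")))
    do.call(rbind, lapply(timecourses, function(tc) {
        pk <- extractPeak(tc)
        data.frame(subjectId = tc@subjectId, group = tc@group, age = tc@age,
                   peak = pk$peak, peakDay = pk$peakDay)
    }))
}
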
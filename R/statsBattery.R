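#' Pooled-variance two-sample t-test with Bonferroni adjustment
#'
#' Classical (Student, equal-variance) two-tailed two-sample t-test; with
#' `corrections > 1` the p value is Bonferroni-adjusted as
#' `min(1, p * corrections)` for use inside a family of planned comparisons.
#' The pooled-variance form gives the classical degrees of freedom
#' `n1 + n2 - 2` (e.g. t(38) for two groups of 20).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param corrections number of comparisons in the family (default 1).
#' @return list with `statistic`, `df`, `p`, `pAdjusted`.
#' @export
twoSampleT <- function(a, b, corrections = 1) {
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs n >= 2")
    if (!all(is.finite(a)) || !all(is.finite(b)))
        stop("samples must be finite")
    if (stats::var(a) == 0 && stats::var(b) == 0 && length(c(a, b)) <= 4 &&
        isTRUE(all.equal(mean(a), mean(b))))
        stop("degenerate samples: zero variance and equal means")
    res <- stats::t.test(a, b, var.equal = TRUE)
    p <- res$p.value
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p = p, pAdjusted = min(1, p * corrections))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p value
#' is the asymptotic one.  Used to compare spine-size distributions and
#' response-magnitude histograms between groups.
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (D) and `p`.
#' @export
ksTwoSample <- function(a, b) {
    if (length(a) == 0 || length(b) == 0)
        stop("both samples must be non-empty")
    res <- suppressWarnings(stats::ks.test(a, b))
    list(statistic = unname(res$statistic), p = res$p.value)
}

#' Mixed (split-plot) repeated-measures ANOVA interaction test
#'
#' Classical repeated-measures ANOVA with one between-subjects factor (group)
#' and one within-subjects factor (e.g. the spine fate category stable /
#' lost / gained measured on every dendritic segment), fitted with
#' `stats::aov` and an `Error(subject)` stratum.  Reports the group x
#' category interaction F with its uncorrected degrees of freedom (no
#' sphericity correction), plus the cell-means table.
#'
#' @param data data.frame in long format.
#' @param value,group,category,subject names of the value, between-group,
#'   within-category and subject columns.
#' @return list with `F`, `df1`, `df2`, `p`, `means` (group x category cell
#'   means), and the full `aov` within-stratum table as `table`.
#' @export
mixedAnova <- function(data, value = "value", group = "group",
                       category = "category", subject = "subject") {
    need <- c(value, group, category, subject)
    if (!all(need %in% names(data)))
        stop("'data' needs columns ", paste(need, collapse = ", "))
    d <- data.frame(value = data[[value]], group = factor(data[[group]]),
                    category = factor(data[[category]]),
                    subject = factor(data[[subject]]))
    if (!all(is.finite(d$value))) stop("values must be finite")
    tab <- table(d$subject, d$category)
    if (any(tab != 1))
        stop("design must be balanced: each subject once per category")
    fit <- stats::aov(value ~ group * category + Error(subject), data = d)
    within <- summary(fit)[["Error: Within"]][[1]]
    ir <- grep("group:category", rownames(within))
    er <- grep("Residuals", rownames(within))
    ssInt <- within[ir, "Sum Sq"]; ssErr <- within[er, "Sum Sq"]
    df1 <- within[ir, "Df"]; df2 <- within[er, "Df"]
    if (ssInt <= .Machine$double.eps * max(1, sum(d$value^2))) {
        Fv <- 0; p <- 1
    } else {
        Fv <- (ssInt / df1) / (ssErr / df2)
        p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    means <- stats::aggregate(value ~ group + category, data = d, FUN = mean)
    list(F = Fv, df1 = df1, df2 = df2, p = p, means = means, table = within)
}

#' Lilliefors test of normality with Monte-Carlo p value
#'
#' Kolmogorov-Smirnov distance between the sample ECDF and a normal
#' distribution with mean and SD estimated from the sample; because the
#' parameters are estimated, the null distribution of the statistic is
#' obtained by seeded Monte-Carlo simulation (default 10,000 standard-normal
#' samples of the same size) rather than from the plain KS tables.  The
#' global random-number state is left untouched.
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @param nsim Monte-Carlo replicates (default 10000).
#' @param mcSeed seed for the null simulation (default 171717).
#' @return list with `statistic` (D) and `p`.
#' @export
lillieforsTest <- function(x, nsim = 10000, mcSeed = 171717) {
    if (length(x) < 4) stop("n >= 4 required")
    if (!all(is.finite(x))) stop("sample must be finite")
    if (stats::sd(x) == 0) stop("constant input")
    D <- .lillieforsD(x)
    n <- length(x)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(mcSeed)
    nullD <- vapply(seq_len(nsim),
                    function(i) .lillieforsD(stats::rnorm(n)), numeric(1))
    list(statistic = D, p = (1 + sum(nullD >= D)) / (nsim + 1))
}

.lillieforsD <- function(x) {
    n <- length(x)
    p <- stats::pnorm(sort(x), mean(x), stats::sd(x))
    i <- seq_len(n)
    max(i / n - p, p - (i - 1) / n)
}
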
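## Per-module enrichment between MAG groups: two-tailed Mann-Whitney U test
## on module completion scores, comparing MAGs expressed at a focal vent
## field or site against all others.

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test of the null hypothesis that the two samples share one
#' distribution, delegated to [stats::wilcox.test()]: an exact p-value is
#' used for small untied samples and the normal approximation with tie and
#' continuity correction otherwise. The U statistic counts pairs
#' \eqn{(a_i, b_j)} with \eqn{a_i > b_j} (midrank ties count 1/2), so
#' swapping the groups maps U to `length(a) * length(b) - U`.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact-enumeration
#'   p-value; `NULL` (default) uses the standard small-sample/no-ties rule.
#' @return list with elements `u` (the U statistic for group `a`), `p`
#'   (two-tailed p-value) and `exact` (logical, which branch was used).
#' @examples
#' mannWhitneyU(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15))  # U = 9, p = 0.1
#' @export
mannWhitneyU <- function(a, b, exact = NULL) {
    if (length(a) == 0L || length(b) == 0L)
        stop("both groups must be non-empty")
    stopifnot(is.numeric(a), is.numeric(b), !anyNA(a), !anyNA(b))
    ties <- anyDuplicated(c(a, b)) > 0L
    if (length(unique(c(a, b))) == 1L) {
        ## all observations identical: no evidence against the null
        return(list(u = length(a) * length(b) / 2, p = 1, exact = FALSE))
    }
    usedExact <- if (is.null(exact)) {
        length(a) < 50 && length(b) < 50 && !ties
    } else {
        isTRUE(exact) && !ties
    }
    wt <- suppressWarnings(stats::wilcox.test(
        a, b, alternative = "two.sided", exact = usedExact,
        correct = TRUE))
    list(u = unname(wt$statistic), p = min(1, wt$p.value),
         exact = usedExact)
}

#' Assign MAGs to expression groups by transcript profile
#'
#' Each MAG is assigned to the vent field (or site) where its summed
#' normalized transcript abundance is maximal; the grouping splits MAGs
#' assigned to the focal label from all others. MAGs with all-zero
#' transcript rows carry no expression signal and are excluded (reported in
#' the result).
#'
#' @param transcript a metatranscriptomic [AbundanceMatrix-class]
#'   (MAGs x samples).
#' @param sampleInfo `data.frame` with columns `sample_id` and the grouping
#'   column(s) `site` and/or `field`, covering every sample column.
#' @param partition assign by `"field"` or `"site"`.
#' @param focal the field/site label defining group A.
#' @return a [MagGrouping-class].
#' @export
assignExpressionGroups <- function(transcript, sampleInfo,
                                   partition = c("field", "site"), focal) {
    stopifnot(is(transcript, "AbundanceMatrix"))
    partition <- match.arg(partition)
    if (!all(c("sample_id", partition) %in% names(sampleInfo)))
        stop("sampleInfo needs columns sample_id and ", partition)
    m <- values(transcript)
    lab <- sampleInfo[[partition]][match(colnames(m),
                                         sampleInfo$sample_id)]
    if (anyNA(lab))
        stop("unmapped sample(s): ",
             paste(colnames(m)[is.na(lab)], collapse = ", "))
    if (!focal %in% lab)
        stop("unknown focal label '", focal, "'; available: ",
             paste(sort(unique(lab)), collapse = ", "))
    zero <- rowSums(m) == 0
    excluded <- rownames(m)[zero]
    m <- m[!zero, , drop = FALSE]
    if (nrow(m) == 0L) stop("no MAG has non-zero transcript abundance")
    ## per-MAG summed abundance per label; argmax, first label on ties
    labels <- unique(lab)
    sums <- vapply(labels, function(l)
        rowSums(m[, lab == l, drop = FALSE]), numeric(nrow(m)))
    sums <- matrix(sums, nrow = nrow(m),
                   dimnames = list(rownames(m), labels))
    assigned <- labels[max.col(sums, ties.method = "first")]
    groupA <- rownames(m)[assigned == focal]
    groupB <- rownames(m)[assigned != focal]
    if (length(groupA) == 0L || length(groupB) == 0L)
        stop("grouping is degenerate: every MAG assigned to ",
             if (length(groupA)) "the focal label" else "other labels")
    new("MagGrouping", groupA = groupA, groupB = groupB,
        label = sprintf("expressed-at-%s vs elsewhere (by %s)",
                        focal, partition),
        excluded = excluded)
}

#' Per-module MCS enrichment between two MAG groups
#'
#' For every module, tests with a two-tailed Mann-Whitney U test whether
#' the module completion scores of group A and group B MAGs come from the
#' same distribution. Results are sorted by p-value; direction is the sign
#' of the group-mean difference.
#'
#' @param mcs an [MCSMatrix-class].
#' @param grouping a [MagGrouping-class]; every grouped MAG must be a row
#'   of `mcs`.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05).
#' @param correction `"none"` (default; raw p-values, as is conventional
#'   when reporting module-level thresholds) or `"benjamini_hochberg"`.
#' @return `data.frame` with one row per module: `module_id`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `u`, `p`, `p_adj`, `significant`, `direction`
#'   (`"A_higher"`, `"B_higher"` or `"tied"`). The test policy used is
#'   attached as attribute `"method"`.
#' @export
enrichModules <- function(mcs, grouping, alpha = 0.05,
                          correction = c("none", "benjamini_hochberg")) {
    stopifnot(is(mcs, "MCSMatrix"), is(grouping, "MagGrouping"))
    correction <- match.arg(correction)
    s <- scores(mcs)
    missing <- setdiff(c(grouping@groupA, grouping@groupB), rownames(s))
    if (length(missing) > 0L)
        stop("grouped MAG(s) missing from the MCS matrix: ",
             paste(missing, collapse = ", "))
    mods <- colnames(s)
    if (length(mods) == 0L) {
        out <- data.frame(module_id = character(0), n_a = integer(0),
                          n_b = integer(0), mean_a = numeric(0),
                          mean_b = numeric(0), u = numeric(0),
                          p = numeric(0), p_adj = numeric(0),
                          significant = logical(0),
                          direction = character(0))
        attr(out, "method") <- "mann-whitney-u two-tailed"
        return(out)
    }
    rows <- lapply(mods, function(mod) {
        a <- s[grouping@groupA, mod]
        b <- s[grouping@groupB, mod]
        mw <- mannWhitneyU(a, b)
        data.frame(module_id = mod, n_a = length(a), n_b = length(b),
                   mean_a = mean(a), mean_b = mean(b), u = mw$u, p = mw$p,
                   direction = if (isTRUE(all.equal(mean(a), mean(b))))
                       "tied" else if (mean(a) > mean(b)) "A_higher"
                       else "B_higher",
                   exact = mw$exact)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- if (correction == "benjamini_hochberg")
        stats::p.adjust(out$p, method = "BH") else out$p
    out$significant <- out$p_adj < alpha
    out <- out[order(out$p, out$module_id),
               c("module_id", "n_a", "n_b", "mean_a", "mean_b", "u", "p",
                 "p_adj", "significant", "direction", "exact")]
    rownames(out) <- NULL
    attr(out, "method") <- paste0(
        "mann-whitney-u two-tailed; exact for small untied samples, ",
        "normal approximation with continuity correction otherwise; ",
        "correction=", correction)
    out
}
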
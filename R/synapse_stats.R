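#' Grouped summaries of active zone lengths
#'
#' Per group: n, mean, SEM (n-1 SD over sqrt(n)), median and quartiles
#' (linear-interpolation quantiles) of the active zone lengths.
#'
#' @param records synapse record data.frame
#'   (see \code{\link{readSynapseTable}}).
#' @param by character vector of grouping columns (e.g.
#'   \code{c("group", "region", "perforated")}).
#' @return data.frame, one row per non-empty group, grouping columns first.
#' @export
lengthSummary <- function(records, by = "group") {
    stopifnot(all(by %in% names(records)))
    key <- interaction(records[by], drop = TRUE, sep = "\r")
    rows <- lapply(levels(key), function(k) {
        sub <- records[key == k, , drop = FALSE]
        if (nrow(sub) < 2) {
            warning("group omitted (fewer than 2 records): ",
                    gsub("\r", " / ", k))
            return(NULL)
        }
        cbind(sub[1, by, drop = FALSE], summaryRow(sub$az_length_um))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Proportion with exact counts
#'
#' Numerator over denominator as exact counts and a percentage rounded to
#' one decimal, the reporting convention of count tables. Accepts counts or
#' logical vectors (numerator restricted to the denominator subset).
#'
#' @param num numerator: a count or a logical vector.
#' @param den denominator: a count or a logical vector.
#' @return list: k, n, fraction, percent (1-decimal).
#' @examples
#' proportion(10, 219)$percent   # 4.6
#' proportion(187, 281)$percent  # 66.5
#' @export
proportion <- function(num, den) {
    if (is.logical(den)) {
        if (!is.logical(num) || length(num) != length(den))
            stop("logical num/den must be same-length vectors")
        k <- sum(num & den); n <- sum(den)
    } else {
        k <- as.numeric(num); n <- as.numeric(den)
    }
    if (n <= 0) stop("zero denominator")
    list(k = k, n = n, fraction = k / n, percent = round(100 * k / n, 1))
}

#' Contingency table test
#'
#' Pearson chi-square by default (df = (r-1)(k-1), no continuity
#' correction), Yates-corrected chi-square or Fisher's exact test on
#' request; two-sided p. With chi-square, an expected cell below 1 triggers
#' a warning suggesting Fisher.
#'
#' @param tab matrix of non-negative integer counts (2 x k typical).
#' @param method "chisq", "yates" or "fisher".
#' @return list: method, statistic (NA for Fisher), p, expected, proportions
#'   (row-normalised), table.
#' @examples
#' tab <- rbind(nonepileptic = c(128, 93, 19), epileptic = c(187, 85, 9))
#' contingencyTest(tab)$p   # ~0.0027
#' @export
contingencyTest <- function(tab, method = c("chisq", "yates", "fisher")) {
    method <- match.arg(method)
    tab <- as.matrix(tab)
    stopifnot(all(tab >= 0), all(tab == round(tab)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (method %in% c("chisq", "yates") && any(expected < 1))
        warning("expected cell count < 1; consider Fisher's exact test")
    res <- switch(method,
        chisq = {
            ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
            list(statistic = unname(ht$statistic), p = ht$p.value)
        },
        yates = {
            ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
            list(statistic = unname(ht$statistic), p = ht$p.value)
        },
        fisher = {
            ht <- stats::fisher.test(tab)
            list(statistic = NA_real_, p = ht$p.value)
        })
    list(method = method, statistic = res$statistic, p = res$p,
         expected = expected, proportions = tab / rowSums(tab), table = tab)
}

#' Dunn's multiple-comparison follow-up test
#'
#' Rank-based pairwise z tests on the pooled ranks after a Kruskal-Wallis
#' test, with tie correction. P values are two-sided; no further adjustment
#' unless requested.
#'
#' @param values numeric vector.
#' @param group grouping factor.
#' @param adjust p.adjust method ("none" default).
#' @return data.frame: group1, group2, z, p, p_adj.
#' @export
dunnTest <- function(values, group, adjust = "none") {
    ok <- is.finite(values) & !is.na(group)
    values <- values[ok]; group <- factor(group[ok])
    N <- length(values)
    r <- rank(values)
    ties <- table(values)
    tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
    meanR <- tapply(r, group, mean)
    n <- tapply(r, group, length)
    g <- levels(group)
    pairs <- utils::combn(g, 2)
    rows <- apply(pairs, 2, function(p) {
        i <- p[1]; j <- p[2]
        se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / n[[i]] + 1 / n[[j]]))
        z <- (meanR[[i]] - meanR[[j]]) / se
        data.frame(group1 = i, group2 = j, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = adjust)
    rownames(out) <- NULL
    out
}

#' Normality-gated group comparison
#'
#' Routes the comparison by the D'Agostino-Pearson normality of every group:
#' all normal (or too small to test) gives ANOVA (t-test for 2 groups),
#' otherwise Kruskal-Wallis (Mann-Whitney for 2 groups) with Dunn's
#' follow-up for more than 2 groups. Groups with fewer than 3 values are
#' excluded with a warning.
#'
#' @param values numeric vector.
#' @param group grouping factor.
#' @param alpha level of the normality gate.
#' @return list: test name, statistic, p, normal (gate outcome), groups
#'   kept, and \code{pairwise} (Dunn table) for rank-based comparisons of
#'   more than 2 groups.
#' @export
groupCompare <- function(values, group, alpha = 0.05) {
    ok <- is.finite(values) & !is.na(group)
    values <- values[ok]; group <- factor(group[ok])
    keep <- names(which(table(group) >= 3))
    if (length(keep) < nlevels(group)) {
        warning("excluding group(s) with n < 3: ",
                paste(setdiff(levels(group), keep), collapse = ", "))
        sel <- group %in% keep
        values <- values[sel]; group <- droplevels(group[sel])
    }
    if (nlevels(group) < 2) stop("need at least 2 groups with n >= 3")
    normal <- all(vapply(levels(group), function(g) {
        p <- dagostinoPearson(values[group == g])$p
        is.na(p) || p >= alpha
    }, logical(1)))
    if (normal) {
        if (nlevels(group) == 2) {
            ht <- stats::t.test(values ~ group)
            res <- list(test = "t", statistic = unname(ht$statistic),
                        p = ht$p.value)
        } else {
            fit <- stats::aov(values ~ group)
            s <- summary(fit)[[1]]
            res <- list(test = "anova", statistic = s$`F value`[1],
                        p = s$`Pr(>F)`[1])
        }
    } else {
        if (nlevels(group) == 2) {
            ht <- suppressWarnings(stats::wilcox.test(values ~ group))
            res <- list(test = "mann-whitney",
                        statistic = unname(ht$statistic), p = ht$p.value)
        } else {
            ht <- stats::kruskal.test(values, group)
            res <- list(test = "kruskal-wallis",
                        statistic = unname(ht$statistic), p = ht$p.value,
                        pairwise = dunnTest(values, group))
        }
    }
    res$normal <- normal
    res$groups <- levels(group)
    res
}

#' Age / epilepsy multiple regression on perforated-synapse fraction
#'
#' Ordinary least squares of the per-patient perforated fraction on patient
#' age and epilepsy status, the control for the age mismatch between
#' patient groups. Both groups must be present (a single group makes the
#' status indicator constant).
#'
#' @param records synapse record table, or a pre-aggregated data.frame with
#'   columns \code{perf_fraction}, \code{age}, \code{group}.
#' @return list: coefficients (estimate, p per predictor), n_patients,
#'   model (the lm fit).
#' @export
ageEpilepsyRegression <- function(records) {
    if (!"perf_fraction" %in% names(records)) {
        ## aggregate active-zone records per patient
        agg <- do.call(rbind, lapply(split(records, records$patient_id),
            function(s) data.frame(
                patient_id = s$patient_id[1], group = s$group[1],
                age = s$age[1],
                perf_fraction = mean(s$perforated))))
        records <- agg
    }
    if (nrow(records) < 4) stop("need at least 4 patients")
    if (length(unique(records$group)) < 2)
        stop("both patient groups required: status indicator is constant")
    records$epileptic <- as.integer(records$group == "epileptic")
    fit <- stats::lm(perf_fraction ~ age + epileptic, data = records)
    cf <- summary(fit)$coefficients
    list(coefficients = data.frame(term = rownames(cf),
                                   estimate = cf[, 1], p = cf[, 4],
                                   row.names = NULL),
         n_patients = nrow(records), model = fit)
}
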
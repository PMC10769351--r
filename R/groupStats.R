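#' Significance stars
#'
#' @param p numeric p-values.
#' @return character: \code{***} below 0.001, \code{**} below 0.01,
#'   \code{*} below 0.05, \code{ns} otherwise.
#' @export
significanceStars <- function(p) {
    ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

dunnFamilyAdjust <- function(pRaw, family) {
    # Bonferroni over the contrast family (reference contrasts by default)
    pmin(1, pRaw * length(pRaw))
}

newStatResult <- function(test, statistic, df, pValue, comparisons,
                          reference, nPerGroup, note = character(0)) {
    new("StatResult", test = test, statistic = statistic, df = df,
        pValue = pValue, comparisons = comparisons, reference = reference,
        nPerGroup = nPerGroup, note = note)
}

#' @rdname comparisons
#' @export
setMethod("comparisons", "StatResult", function(x) x@comparisons)

setMethod("show", "StatResult", function(object) {
    cat(object@test, "\n")
    st <- object@statistic
    for (i in seq_along(st))
        cat(sprintf("  %s = %.4g (df = %s), p = %.4g\n",
                    if (!is.null(names(st))) names(st)[i] else "statistic",
                    st[i],
                    paste(signif(object@df, 4), collapse = ", "),
                    object@pValue[min(i, length(object@pValue))]))
    if (nrow(object@comparisons)) {
        cat("  post-hoc vs '", object@reference, "':\n", sep = "")
        print(object@comparisons, row.names = FALSE, digits = 4)
    }
    if (length(object@note)) cat("  note:", object@note, "\n")
    invisible(NULL)
})

checkConditionTable <- function(data, value, condition) {
    for (col in c(value, condition))
        if (!col %in% names(data)) stop("missing column '", col, "'")
    if (anyNA(data[[value]])) stop("NA observation values")
    invisible(NULL)
}

#' Kruskal-Wallis test with Dunn's control-referenced post hoc
#'
#' Global Kruskal-Wallis across all conditions (midranks for ties),
#' followed by Dunn's rank-sum z tests comparing each condition to the
#' designated reference (e.g. the knockout background), with tie-corrected
#' pooled variance and Bonferroni adjustment over the reference-contrast
#' family. Set \code{family = "all"} for all pairwise contrasts instead.
#'
#' @param data data.frame with one row per sampling unit (synapse, image
#'   or cell, per the analysis).
#' @param reference reference condition label.
#' @param value,condition column names.
#' @param family \code{"reference"} (default) or \code{"all"}.
#' @return a \linkS4class{StatResult}.
#' @export
kruskalDunn <- function(data, reference, value = "value",
                        condition = "condition",
                        family = c("reference", "all")) {
    family <- match.arg(family)
    checkConditionTable(data, value, condition)
    g <- factor(data[[condition]])
    y <- data[[value]]
    if (nlevels(g) < 2L)
        stop("need at least two conditions, got ", nlevels(g))
    if (any(table(g) < 2L)) stop("every condition needs >= 2 observations")
    if (!reference %in% levels(g))
        stop("reference condition '", reference, "' not present")
    kw <- stats::kruskal.test(y, g)
    # Dunn: z on mean ranks with tie correction
    N <- length(y)
    r <- rank(y)                               # midranks
    ties <- table(r)
    tieC <- sum(ties^3 - ties) / (12 * (N - 1))
    rbar <- tapply(r, g, mean)
    n <- table(g)
    pairs <- if (family == "reference")
        lapply(setdiff(levels(g), reference), function(l) c(l, reference))
    else utils::combn(levels(g), 2, simplify = FALSE)
    cmp <- do.call(rbind, lapply(pairs, function(pr) {
        se <- sqrt((N * (N + 1) / 12 - tieC) *
                   (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
        z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
        data.frame(comparison = paste(pr[1], "vs", pr[2]),
                   n_1 = n[[pr[1]]], n_2 = n[[pr[2]]],
                   estimate = z, p_raw = 2 * stats::pnorm(-abs(z)))
    }))
    cmp$p_adj <- dunnFamilyAdjust(cmp$p_raw)
    cmp$stars <- significanceStars(cmp$p_adj)
    newStatResult(
        "Kruskal-Wallis with Dunn's multiple comparisons",
        c(chi_squared = unname(kw$statistic)), unname(kw$parameter),
        unname(kw$p.value), cmp, reference,
        stats::setNames(as.integer(n), levels(g)))
}

#' Friedman test with Dunn's post hoc versus a reference phase
#'
#' Friedman rank test across within-subject phases with cells as complete
#' blocks (e.g. IPSC amplitude before / after each blocker wash-in),
#' followed by Dunn's z tests of each phase against the reference phase
#' using within-block rank sums, Bonferroni-adjusted over the family.
#'
#' @param data data.frame.
#' @param reference reference phase label (e.g. \code{"before"}).
#' @param value,phase,block column names; blocks are the recorded cells.
#' @return a \linkS4class{StatResult}.
#' @export
friedmanDunn <- function(data, reference = "before", value = "value",
                         phase = "phase", block = "cell") {
    checkConditionTable(data, value, phase)
    if (!block %in% names(data)) stop("missing column '", block, "'")
    ph <- factor(data[[phase]])
    bl <- factor(data[[block]])
    if (!reference %in% levels(ph))
        stop("reference phase '", reference, "' not present")
    tab <- table(bl, ph)
    bad <- rownames(tab)[rowSums(tab == 1L) != nlevels(ph)]
    if (length(bad))
        stop("incomplete blocks (each cell needs every phase exactly ",
             "once): ", paste(bad, collapse = ", "))
    y <- data[[value]]
    fr <- stats::friedman.test(y, ph, bl)
    note <- character(0)
    if (is.nan(fr$statistic)) {
        # every block fully tied: no rank variation at all
        fr$statistic[] <- 0
        fr$p.value <- 1
        note <- "all within-block ranks tied; statistic 0 by convention"
    }
    k <- nlevels(ph); nb <- nlevels(bl)
    # within-block midranks
    rk <- stats::ave(y, bl, FUN = rank)
    rbar <- tapply(rk, ph, mean)
    se <- sqrt(k * (k + 1) / (6 * nb))
    others <- setdiff(levels(ph), reference)
    cmp <- do.call(rbind, lapply(others, function(l) {
        z <- (rbar[[l]] - rbar[[reference]]) / se
        data.frame(comparison = paste(l, "vs", reference),
                   n_1 = nb, n_2 = nb, estimate = z,
                   p_raw = 2 * stats::pnorm(-abs(z)))
    }))
    cmp$p_adj <- dunnFamilyAdjust(cmp$p_raw)
    cmp$stars <- significanceStars(cmp$p_adj)
    newStatResult(
        "Friedman with Dunn's multiple comparisons",
        c(chi_squared = unname(fr$statistic)), unname(fr$parameter),
        unname(fr$p.value), cmp, reference,
        stats::setNames(rep(nb, k), levels(ph)), note = note)
}

#' Normalize within-subject values to a baseline phase
#'
#' Divides every cell's values by that cell's value in the baseline phase
#' (making the baseline identically 1), the scale on which normalized
#' response time courses are compared across genotypes.
#'
#' @param data data.frame.
#' @param baseline baseline phase label.
#' @param value,phase,block column names.
#' @return data.frame with \code{value} replaced by the normalized value.
#' @export
normalizeToPhase <- function(data, baseline = "before", value = "value",
                             phase = "phase", block = "cell") {
    checkConditionTable(data, value, phase)
    base <- data[data[[phase]] == baseline, ]
    if (!nrow(base)) stop("baseline phase '", baseline, "' not present")
    key <- stats::setNames(base[[value]], base[[block]])
    if (anyNA(key[as.character(data[[block]])]))
        stop("cells without a baseline observation")
    if (any(key == 0)) stop("zero baseline value; cannot normalize")
    data[[value]] <- data[[value]] / key[as.character(data[[block]])]
    data
}

#' Two-way repeated-measures ANOVA with Dunnett's post hoc
#'
#' Classic split-plot ANOVA (between factor: genotype; within factor:
#' phase, repeated on cells) via \code{aov} with an \code{Error(cell)}
#' stratum, followed by Dunnett contrasts of each genotype against the
#' reference genotype on the estimated marginal means (emmeans,
#' multivariate-t adjustment). For blocker time courses the conventional
#' input scale is the response normalized to the "before" phase
#' (see [normalizeToPhase()]).
#'
#' @param data data.frame.
#' @param reference reference genotype label.
#' @param value,genotype,phase,block column names.
#' @return a \linkS4class{StatResult} with statistics for the genotype,
#'   phase and interaction effects.
#' @export
rmAnovaDunnett <- function(data, reference, value = "value",
                           genotype = "genotype", phase = "phase",
                           block = "cell") {
    checkConditionTable(data, value, genotype)
    d <- data.frame(value = data[[value]],
                    genotype = factor(data[[genotype]]),
                    phase = factor(data[[phase]]),
                    cell = factor(data[[block]]))
    if (nlevels(d$genotype) < 2L) stop("need at least two genotypes")
    if (!reference %in% levels(d$genotype))
        stop("reference genotype '", reference, "' not present")
    tab <- table(d$cell, d$phase)
    if (any(tab[rowSums(tab) > 0, ] != 1L))
        stop("unbalanced within-subject design: every cell needs each ",
             "phase exactly once")
    d$genotype <- stats::relevel(d$genotype, reference)
    # embed the data in the call so emmeans can re-fit with sum contrasts
    fit <- do.call(stats::aov,
                   list(value ~ genotype * phase + Error(cell), data = d))
    sm <- summary(fit)
    btw <- sm[["Error: cell"]][[1]]
    wth <- sm[["Error: Within"]][[1]]
    pick <- function(tb, term) {
        i <- match(term, trimws(rownames(tb)))
        c(F = tb[i, "F value"], df = tb[i, "Df"], p = tb[i, "Pr(>F)"])
    }
    g <- pick(btw, "genotype")
    p <- pick(wth, "phase")
    gp <- pick(wth, "genotype:phase")
    emm <- suppressMessages(emmeans::emmeans(fit, "genotype", data = d))
    dn <- as.data.frame(emmeans::contrast(emm, method = "trt.vs.ctrl",
                                          ref = 1))
    n <- table(d$genotype[!duplicated(d$cell)])
    cmp <- data.frame(
        comparison = paste(sub(" - .*$", "", dn$contrast), "vs", reference),
        n_1 = as.integer(n[sub(" - .*$", "", dn$contrast)]),
        n_2 = as.integer(n[[reference]]),
        estimate = dn$estimate, p_raw = NA_real_, p_adj = dn$p.value,
        stars = significanceStars(dn$p.value))
    newStatResult(
        "Two-way repeated-measures ANOVA with Dunnett's multiple comparisons",
        c(genotype_F = unname(g["F"]), phase_F = unname(p["F"]),
          interaction_F = unname(gp["F"])),
        c(genotype = unname(g["df"]), phase = unname(p["df"]),
          interaction = unname(gp["df"])),
        c(genotype = unname(g["p"]), phase = unname(p["p"]),
          interaction = unname(gp["p"])),
        cmp, reference, stats::setNames(as.integer(n), names(n)),
        note = "Dunnett p-values are multiplicity-adjusted; p_raw not defined")
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Exact two-sided signed-rank p-value when the sample is small and free
#' of ties/zeros (the default \code{wilcox.test} rule), normal
#' approximation otherwise. All-zero differences are degenerate and
#' reported as p = 1 with a note rather than an error.
#'
#' @param x,y paired observation vectors (same length, same units).
#' @return a \linkS4class{StatResult}.
#' @export
wilcoxonPaired <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must be paired")
    d <- x - y
    if (all(d == 0))
        return(newStatResult(
            "Wilcoxon matched-pairs signed rank test",
            c(V = length(x) * (length(x) + 1) / 4), NA_real_, 1,
            data.frame(), "paired",
            c(pairs = length(x)),
            note = "all paired differences are zero; test degenerate, p = 1"))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    newStatResult(
        "Wilcoxon matched-pairs signed rank test",
        c(V = unname(wt$statistic)), NA_real_, unname(wt$p.value),
        data.frame(), "paired", c(pairs = length(x)))
}

#' Plain-text report of one or more test results
#'
#' @param results a \linkS4class{StatResult} or list of them.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStatReport <- function(results, path) {
    if (is(results, "StatResult")) results <- list(results)
    con <- file(path, "w")
    on.exit(close(con))
    for (r in results) {
        sink(con)
        show(r)
        cat("\n")
        sink()
    }
    invisible(path)
}
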
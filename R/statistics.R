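#' Normality-gated two-group comparison
#'
#' The two-group testing scheme used throughout the pipeline: each
#' group's normality is tested (Shapiro-Wilk by default; a
#' Kolmogorov-Smirnov override is available); if both groups pass at
#' `alpha`, an unpaired two-sided Welch t test is used, otherwise a
#' two-sided Mann-Whitney U test. Constant-valued groups, for which
#' normality is undefined, fall through to Mann-Whitney with a warning.
#'
#' @param a,b numeric vectors (n >= 3 per group for the normality gate).
#' @param alpha significance level of the normality gate (default 0.05).
#' @param normality `"shapiro"` (default) or `"ks"` (Lilliefors-style
#'   KS against a normal with the sample's moments).
#' @return list `test` ("welch" or "mann-whitney"), `statistic`,
#'   `p.value`, `normality_p` (length 2), `n` (length 2).
#' @export
auto_compare_two_groups <- function(a, b, alpha = 0.05,
                                    normality = c("shapiro", "ks")) {
  normality <- match.arg(normality)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("need n >= 3 per group for the normality gate")
  norm_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    if (normality == "shapiro") stats::shapiro.test(x)$p.value
    else suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  pa <- norm_p(a); pb <- norm_p(b)
  if (is.na(pa) || is.na(pb)) {
    warning("constant-valued group: normality undefined, using Mann-Whitney")
    gaussian <- FALSE
  } else {
    gaussian <- pa > alpha && pb > alpha
  }
  if (gaussian) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test <- "welch"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    test <- "mann-whitney"
  }
  list(test = test, statistic = unname(ht$statistic),
       p.value = ht$p.value, normality_p = c(a = pa, b = pb),
       n = c(a = length(a), b = length(b)))
}

#' Association test for categorical data
#'
#' Chi-squared test without continuity correction for adequately filled
#' tables; Fisher's exact test when any expected count is below 5 (the
#' small-sample rule) or on request. A one-dimensional count vector is
#' tested against given (default uniform) proportions. The
#' `straightness` mode first bins values into `[0, 0.1), ..., [0.9, 1]`
#' per group, the scheme used for comparing track-straightness
#' distributions.
#'
#' @param x a contingency table/matrix of counts, or (straightness
#'   mode) a numeric vector of straightness values.
#' @param mode `"auto"`, `"chisq"`, `"fisher"` or `"straightness"`.
#' @param p expected proportions for a 1-d goodness-of-fit test.
#' @param groups group labels (required for straightness mode).
#' @return list `test`, `statistic` (NA for Fisher), `p.value`,
#'   `table`.
#' @export
categorical_association <- function(x, mode = c("auto", "chisq",
                                                "fisher", "straightness"),
                                    p = NULL, groups = NULL) {
  mode <- match.arg(mode)
  if (mode == "straightness") {
    if (is.null(groups)) stop("straightness mode needs group labels")
    br <- seq(0, 1, by = 0.1)
    bin <- cut(pmin(pmax(x, 0), 1), breaks = br, right = FALSE,
               include.lowest = TRUE)
    x <- table(groups, bin)
    mode <- "chisq"
  }
  if (is.null(dim(x))) {
    ## goodness of fit
    if (any(x < 0) || any(x != round(x)))
      stop("counts must be nonnegative integers")
    if (is.null(p)) p <- rep(1 / length(x), length(x))
    ht <- stats::chisq.test(x, p = p, correct = FALSE)
    return(list(test = "chisq-gof", statistic = unname(ht$statistic),
                p.value = ht$p.value, table = x))
  }
  tab <- as.matrix(x)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (any(dim(tab) < 2)) stop("table degenerate after dropping margins")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  small <- any(expected < 5)
  if (mode == "fisher" || (mode == "auto" && small)) {
    ht <- stats::fisher.test(tab)
    return(list(test = "fisher", statistic = NA_real_,
                p.value = ht$p.value, table = tab))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = "chisq", statistic = unname(ht$statistic),
       p.value = ht$p.value, table = tab)
}

#' Relative expression by the ddCt method
#'
#' Technical replicates are averaged per sample and gene; per condition,
#' `dCt = Cq_gene - Cq_reference`; `ddCt = dCt_condition - dCt_control`;
#' reported expression is `100 * 2^-ddCt` percent of the control. The
#' result is invariant to any per-sample additive Cq offset shared by
#' target and reference (a plate offset cancels in the differences).
#'
#' @param cq data.frame with `condition`, `gene`, `cq` (one row per
#'   technical replicate).
#' @param reference_gene housekeeping gene name (default "HPRT").
#' @param control control condition label.
#' @return data.frame `gene`, `condition`, `ddct`, `percent_expression`.
#' @export
ddct_expression <- function(cq, reference_gene = "HPRT",
                            control = "control") {
  need <- c("condition", "gene", "cq")
  if (!all(need %in% names(cq)))
    stop("cq needs columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(cq ~ condition + gene, cq, mean)
  conds <- unique(agg$condition)
  if (!control %in% conds) stop("control condition not found: ", control)
  ref <- agg[agg$gene == reference_gene, ]
  if (nrow(ref) == 0) stop("reference gene not found: ", reference_gene)
  if (!all(conds %in% ref$condition))
    stop("missing reference-gene Cq for condition(s): ",
         paste(setdiff(conds, ref$condition), collapse = ", "))
  genes <- setdiff(unique(agg$gene), reference_gene)
  rows <- list()
  for (g in genes) {
    sub <- agg[agg$gene == g, ]
    dct <- sub$cq - ref$cq[match(sub$condition, ref$condition)]
    dct_ctrl <- dct[sub$condition == control]
    if (!length(dct_ctrl)) stop("no control Cq for gene ", g)
    ddct <- dct - dct_ctrl
    rows[[g]] <- data.frame(gene = g, condition = sub$condition,
                            ddct = ddct,
                            percent_expression = 100 * 2^(-ddct))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize values to the control mean within experiment blocks
#'
#' Within each experiment, all values are divided by the mean of the
#' control replicates, so the control mean is exactly 1 afterwards —
#' the "normalized to the average of controls (set at 1) in each
#' experiment" convention.
#'
#' @param values numeric vector.
#' @param group group label per value.
#' @param experiment experiment block per value (default: one block).
#' @param control control group label.
#' @return numeric vector of normalized values.
#' @export
normalize_to_control <- function(values, group,
                                 experiment = rep(1L, length(values)),
                                 control = "control") {
  out <- rep(NA_real_, length(values))
  for (b in unique(experiment)) {
    sel <- experiment == b
    ctrl <- values[sel & group == control]
    if (!length(ctrl)) stop("no control replicate in experiment ", b)
    m <- mean(ctrl)
    if (!is.finite(m) || m <= 0)
      stop("control mean <= 0 in experiment ", b)
    out[sel] <- values[sel] / m
  }
  out
}

#' One-way fixed-effects ANOVA on group values
#'
#' Omnibus comparison across more than two groups (the grouped-data
#' panels); post hoc pairwise comparisons are out of scope.
#'
#' @param values numeric vector.
#' @param group group label per value.
#' @return list `statistic` (F), `df`, `p.value`.
#' @export
anova_groups <- function(values, group) {
  fit <- stats::aov(values ~ factor(group))
  s <- summary(fit)[[1]]
  list(statistic = s[["F value"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       p.value = s[["Pr(>F)"]][1])
}
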
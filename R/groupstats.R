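#' Paired t-tests on post-condition ratings
#'
#' Two-sided paired t-test (df = n - 1) per rating scale between the two
#' conditions.  Scales with zero-variance differences return t = 0,
#' p = 1 with a warning.
#'
#' @param subjects subject table with columns `<scale>_<condition>`.
#' @param scales rating scale names (default the five slider scales).
#' @param conditions the two condition labels.
#' @return data frame: scale, t, df, p.
#' @export
paired_ratings_tests <- function(subjects,
                                 scales = c("pss", "rumination", "valence",
                                            "arousal", "dominance"),
                                 conditions = c("natural", "built")) {
  stopifnot(nrow(subjects) >= 3)
  out <- lapply(scales, function(sc) {
    a <- subjects[[paste(sc, conditions[1], sep = "_")]]
    b <- subjects[[paste(sc, conditions[2], sep = "_")]]
    if (is.null(a) || is.null(b)) stop("missing rating columns for ", sc)
    d <- a - b
    if (stats::sd(d) == 0) {
      warning("zero-variance differences for scale ", sc)
      return(data.frame(scale = sc, t = 0, df = length(d) - 1, p = 1))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(scale = sc, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  do.call(rbind, out)
}

#' Mean connectivity over a component's edges
#'
#' For each subject and condition, the arithmetic mean of the Pearson r
#' values over the component's edges (per-edge values retained for the
#' exploratory follow-up).
#'
#' @param stacked output of [stack_condition_matrices()].
#' @param component_edges integer vector of canonical edge rows (e.g. an
#'   NBS component's `edges` or the generator's `planted_edge_rows`).
#' @return list with `mean_r` (subject x condition matrix), `per_edge`
#'   (list per condition of subject x edge matrices), `edge_index` rows.
#' @export
component_mean_connectivity <- function(stacked, component_edges) {
  if (length(component_edges) == 0) stop("empty component")
  stopifnot(all(component_edges >= 1),
            all(component_edges <= nrow(stacked$edge_index)))
  conds <- names(stacked$conditions)
  per_edge <- lapply(stacked$conditions, function(m) {
    m[, component_edges, drop = FALSE]
  })
  mean_r <- vapply(per_edge, rowMeans, numeric(length(stacked$subjects)))
  list(mean_r = mean_r, per_edge = per_edge,
       edges = stacked$edge_index[component_edges, , drop = FALSE],
       subjects = stacked$subjects)
}

#' Correlation of component connectivity with a subject covariate
#'
#' Pearson correlation (two-sided p, df = n - 2) between the per-subject
#' mean component connectivity in one condition and a covariate (e.g.
#' years of urban upbringing).  Per-edge exploratory correlations are
#' computed only when the mean-level correlation is significant at
#' `alpha` (mirroring the gated follow-up design); a BH-corrected column
#' accompanies the uncorrected exploratory p-values.
#'
#' @param cc output of [component_mean_connectivity()].
#' @param covariate per-subject values, aligned with `cc$subjects`.
#' @param condition which condition's connectivity to correlate.
#' @param alpha gate for the exploratory follow-up (default 0.05).
#' @return list with `r`, `df`, `p`, `n`, and `per_edge` (data frame or
#'   NULL when the gate is closed).
#' @export
covariate_correlation <- function(cc, covariate, condition = "natural",
                                  alpha = 0.05) {
  y <- cc$mean_r[, condition]
  n <- length(y)
  stopifnot(length(covariate) == n, n >= 4)
  if (stats::sd(covariate) == 0) stop("constant covariate")
  ct <- stats::cor.test(covariate, y)
  per_edge <- NULL
  if (ct$p.value <= alpha) {
    pe <- cc$per_edge[[condition]]
    rows <- lapply(seq_len(ncol(pe)), function(k) {
      ek <- stats::cor.test(covariate, pe[, k])
      data.frame(roi_i = cc$edges[k, "i"], roi_j = cc$edges[k, "j"],
                 r = unname(ek$estimate), p = ek$p.value)
    })
    per_edge <- do.call(rbind, rows)
    per_edge$p_adjusted <- stats::p.adjust(per_edge$p, method = "BH")
  }
  list(r = unname(ct$estimate), df = n - 2, p = ct$p.value, n = n,
       per_edge = per_edge)
}

#' Mixed ANOVA after splitting the urbanicity covariate
#'
#' Splits subjects into low (<= 5 years) and high (>= 10 years) urban
#' upbringing, excluding intermediates, and fits a 2 (condition, within)
#' x 2 (group, between) repeated-measures ANOVA on mean component
#' connectivity via [stats::aov()] with a subject error stratum.
#'
#' @param cc output of [component_mean_connectivity()].
#' @param years_urban per-subject values aligned with `cc$subjects`.
#' @param low,high split bounds (defaults 5 and 10).
#' @return data frame: effect (group, condition, condition:group), df1,
#'   df2, F, p; plus attribute `n_excluded`.
#' @export
urban_split_anova <- function(cc, years_urban, low = 5, high = 10) {
  stopifnot(length(years_urban) == nrow(cc$mean_r))
  grp <- ifelse(years_urban <= low, "low",
                ifelse(years_urban >= high, "high", NA))
  keep <- !is.na(grp)
  if (sum(grp[keep] == "low") < 2 || sum(grp[keep] == "high") < 2) {
    stop("each urbanicity group needs at least 2 subjects after exclusion")
  }
  conds <- colnames(cc$mean_r)
  dat <- data.frame(
    subject = factor(rep(cc$subjects[keep], 2)),
    group = factor(rep(grp[keep], 2), levels = c("low", "high")),
    condition = factor(rep(conds, each = sum(keep)), levels = conds),
    y = c(cc$mean_r[keep, 1], cc$mean_r[keep, 2]))
  fit <- stats::aov(y ~ condition * group + Error(subject / condition),
                    data = dat)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: subject:condition"]][[1]])
  pick <- function(tab, term) {
    k <- grep(paste0("^", term, "\\s*$"), rownames(tab))
    res_k <- grep("Residuals", rownames(tab))
    data.frame(effect = term, df1 = tab$Df[k], df2 = tab$Df[res_k],
               F = tab$`F value`[k], p = tab$`Pr(>F)`[k])
  }
  out <- rbind(pick(between, "group"),
               pick(within, "condition"),
               pick(within, "condition:group"))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Confound check: covariate vs global signal fluctuation
#'
#' Pearson correlation of the covariate with per-subject GSF averaged over
#' the two conditions.
#'
#' @param gsf_by_condition subject x condition matrix (or data frame) of
#'   GSF values.
#' @param covariate per-subject values.
#' @return list with `r`, `df`, `p`, `n`.
#' @export
gsf_confound_check <- function(gsf_by_condition, covariate) {
  g <- rowMeans(as.matrix(gsf_by_condition))
  n <- length(g)
  stopifnot(length(covariate) == n, n >= 4)
  if (stats::sd(g) == 0) stop("zero-variance GSF")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  ct <- stats::cor.test(covariate, g)
  list(r = unname(ct$estimate), df = n - 2, p = ct$p.value, n = n)
}
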
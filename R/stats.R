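# Group statistics for pipeline outputs: one-way ANOVA with Holm-corrected
# pairwise contrasts, split-plot ("mixed") ANOVA for group x time-bin designs
# with Tukey-Kramer comparisons, Welch t tests with Bonferroni correction,
# and the hourly event/wake Pearson correlation.

#' One-way ANOVA with Holm-corrected pairwise contrasts
#'
#' Classical one-way F test plus pairwise t contrasts sharing the pooled
#' within-group variance, step-down Holm adjusted.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param contrasts Optional list of `c(a, b)` group pairs; default all pairs.
#' @return List with `F`, `df`, `p`, `ms_within`, and a data frame
#'   `contrasts` (`t`, `p_raw`, `p_holm`).  Degenerate (zero within-group
#'   variance) designs are flagged with `degenerate = TRUE` and limit-case
#'   p-values.
#' @export
one_way_anova_holm <- function(values, groups, contrasts = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("need at least two values per group")
  n <- length(values)
  g <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  ss_b <- sum(ng * (gm - mean(values))^2)
  ss_w <- sum((values - gm[groups])^2)
  df1 <- g - 1
  df2 <- n - g
  ms_w <- ss_w / df2
  degenerate <- ms_w <= 0
  f <- if (degenerate) {
    if (ss_b > 0) Inf else 0
  } else (ss_b / df1) / ms_w
  p <- if (degenerate) {
    if (ss_b > 0) 0 else 1
  } else pf(f, df1, df2, lower.tail = FALSE)
  if (is.null(contrasts)) {
    lev <- levels(groups)
    contrasts <- utils::combn(lev, 2, simplify = FALSE)
  }
  ct <- do.call(rbind, lapply(contrasts, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(ms_w * (1 / ng[match(i, levels(groups))] +
                         1 / ng[match(j, levels(groups))]))
    t <- if (se > 0) (gm[[i]] - gm[[j]]) / se else
      if (gm[[i]] == gm[[j]]) 0 else Inf * sign(gm[[i]] - gm[[j]])
    data.frame(a = i, b = j, t = t,
               p_raw = if (is.finite(t)) 2 * pt(-abs(t), df2) else 0)
  }))
  ct$p_holm <- stats::p.adjust(ct$p_raw, method = "holm")
  list(F = f, df = c(df1, df2), p = p, ms_within = ms_w,
       degenerate = degenerate, contrasts = ct)
}

#' Split-plot (mixed) ANOVA for group x time-bin designs
#'
#' Treatment group is a between-animal fixed effect; time bin is a repeated
#' (within-animal) factor; the animal is the experimental unit, so the group
#' effect is tested against between-animal variation (equivalently, on
#' per-animal means).  Bin and group-by-bin effects are tested in the
#' within-animal stratum.  Pairwise group comparisons use the Tukey-Kramer
#' studentized-range adjustment, which reduces to Tukey's HSD for balanced
#' designs.
#'
#' @param data Data frame with columns `value`, `group`, `bin`, `animal_id`;
#'   one value per animal and bin.
#' @param interaction Include the group:bin interaction term.
#' @return List: `group` (`F`, `df`, `p`), `bin`, `interaction` (when
#'   requested), and data frame `tukey` of pairwise group results.
#' @export
mixed_anova <- function(data, interaction = TRUE) {
  stopifnot(all(c("value", "group", "bin", "animal_id") %in% names(data)))
  data$group <- factor(data$group)
  data$bin <- factor(data$bin)
  data$animal_id <- factor(data$animal_id)
  nb <- nlevels(data$bin)
  g <- nlevels(data$group)
  # between-animal stratum == one-way ANOVA on per-animal means
  am <- stats::aggregate(value ~ animal_id + group, data, mean)
  if (any(table(am$group) < 2))
    stop("insufficient replication: need >= 2 animals per group")
  if (nb < 2) {
    warning("single time bin: degenerates to one-way ANOVA on animal means")
    ow <- one_way_anova_holm(am$value, am$group)
    return(list(group = list(F = ow$F, df = ow$df, p = ow$p),
                bin = NULL, interaction = NULL,
                tukey = tukey_kramer(am$value, am$group, ow$ms_within,
                                     ow$df[2])))
  }
  ow <- one_way_anova_holm(am$value, am$group)
  # within-animal stratum: remove animal means, test bin (+ interaction)
  centred <- data
  centred$value <- data$value -
    am$value[match(paste(data$animal_id), paste(am$animal_id))]
  wfit <- stats::anova(lm(if (interaction) value ~ bin + bin:group
                          else value ~ bin, data = centred))
  n_animals <- nrow(am)
  df_bin <- nb - 1
  df_int <- (g - 1) * (nb - 1)
  df_res <- (n_animals - g) * (nb - 1)
  ss_bin <- wfit["bin", "Sum Sq"]
  ss_int <- if (interaction) wfit["bin:group", "Sum Sq"] else 0
  ss_res <- wfit["Residuals", "Sum Sq"]
  if (!interaction) df_res <- df_res + df_int
  ms_res <- ss_res / df_res
  f_bin <- (ss_bin / df_bin) / ms_res
  res <- list(
    group = list(F = ow$F, df = ow$df, p = ow$p),
    bin = list(F = f_bin, df = c(df_bin, df_res),
               p = pf(f_bin, df_bin, df_res, lower.tail = FALSE)),
    interaction = NULL,
    tukey = tukey_kramer(am$value, am$group, ow$ms_within, ow$df[2]))
  if (interaction) {
    f_int <- (ss_int / df_int) / ms_res
    res$interaction <- list(F = f_int, df = c(df_int, df_res),
                            p = pf(f_int, df_int, df_res,
                                   lower.tail = FALSE))
  }
  res
}

#' Tukey-Kramer pairwise comparisons
#'
#' @param means Values (per experimental unit).
#' @param groups Group labels.
#' @param ms_err Error mean square from the appropriate stratum.
#' @param df_err Its degrees of freedom.
#' @return Data frame: `a`, `b`, `diff`, `q`, `p_adj`.
#' @export
tukey_kramer <- function(means, groups, ms_err, df_err) {
  groups <- factor(groups)
  g <- nlevels(groups)
  gm <- tapply(means, groups, mean)
  ng <- tabulate(groups)
  prs <- utils::combn(levels(groups), 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    i <- match(pr[1], levels(groups)); j <- match(pr[2], levels(groups))
    se <- sqrt(ms_err / 2 * (1 / ng[i] + 1 / ng[j]))
    q <- if (se > 0) abs(gm[i] - gm[j]) / se else
      if (gm[i] == gm[j]) 0 else Inf
    data.frame(a = pr[1], b = pr[2], diff = gm[[i]] - gm[[j]], q = q,
               p_adj = if (is.finite(q))
                 ptukey(q, g, df_err, lower.tail = FALSE) else 0)
  }))
}

#' Bonferroni correction by multiplication
#'
#' Multiplies a p-value by the number of comparisons; the capped form
#' truncates at 1 (the uncapped product is reported alongside it in
#' [welch_bonferroni()] for fidelity with sources that print values above 1).
#'
#' @param p Raw p-value(s). @param m Number of comparisons.
#' @param cap Truncate at 1.
#' @return Corrected p-value(s).
#' @export
bonferroni_correct <- function(p, m, cap = TRUE) {
  out <- p * m
  if (cap) pmin(1, out) else out
}

#' Welch two-sample t tests with Bonferroni correction
#'
#' Unequal-variance t tests for a set of planned group pairs; each p-value
#' is multiplied by the number of comparisons.  The product is capped at 1
#' (`p_bonferroni`); the uncapped product is kept in `p_bonferroni_uncapped`.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param pairs List of `c(a, b)` group pairs to compare.
#' @return Data frame per pair: `t`, `df` (Welch-Satterthwaite), `p_raw`,
#'   `p_bonferroni`, `p_bonferroni_uncapped`.
#' @export
welch_bonferroni <- function(values, groups, pairs) {
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("insufficient replication: need >= 2 animals per compared group")
    vx <- var(x) / length(x)
    vy <- var(y) / length(y)
    if (vx + vy == 0) {
      t <- 0; df <- length(x) + length(y) - 2; p <- 1
    } else {
      t <- (mean(x) - mean(y)) / sqrt(vx + vy)
      df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
      p <- 2 * pt(-abs(t), df)
    }
    data.frame(a = pr[1], b = pr[2], t = t, df = df, p_raw = p,
               p_bonferroni = bonferroni_correct(p, m),
               p_bonferroni_uncapped = bonferroni_correct(p, m, cap = FALSE))
  }))
}

#' Pearson correlation of hourly event counts and wake minutes
#'
#' @param events_per_hour Hourly event counts.
#' @param wake_min_per_hour Hourly wake minutes (same length).
#' @return List: `r`, `r2`, `p`, `n`; `r` is `NA` with a note when either
#'   series has zero variance.
#' @export
hourly_event_wake_correlation <- function(events_per_hour,
                                          wake_min_per_hour) {
  stopifnot(length(events_per_hour) == length(wake_min_per_hour))
  if (length(events_per_hour) < 3)
    stop("need at least 3 paired hours")
  if (sd(events_per_hour) == 0 || sd(wake_min_per_hour) == 0) {
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_,
                n = length(events_per_hour),
                note = "undefined correlation: zero variance"))
  }
  ct <- cor.test(events_per_hour, wake_min_per_hour, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(events_per_hour))
}

#' Descriptive skewness per group
#'
#' Reported for inspection only; no gating is applied.
#'
#' @param values Numeric response. @param groups Group labels.
#' @return Data frame per group: `n`, `skewness` (adjusted Fisher-Pearson).
#' @export
skewness_report <- function(values, groups) {
  groups <- factor(groups)
  do.call(rbind, lapply(levels(groups), function(gr) {
    x <- values[groups == gr]
    n <- length(x)
    sk <- if (n > 2 && sd(x) > 0)
      n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / sd(x))^3)
    else NA_real_
    data.frame(group = gr, n = n, skewness = sk)
  }))
}
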
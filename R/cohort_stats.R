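#' Per-group mean and SEM of clamp endpoints
#'
#' @param results data.frame of per-animal results (one row per animal),
#'   e.g. from rbind-ing [analyze_record()] rows.
#' @param endpoints character vector of numeric columns to summarize.
#' @param by grouping columns (default diet and state).
#' @return data.frame with one row per group x endpoint: group labels, `n`,
#'   `mean`, `sem` (NA when n = 1: a single animal has no standard error).
#' @export
summarize_groups <- function(results,
                             endpoints = c("Rd_basal", "Rd_SS", "EGP_basal",
                                           "EGP_SS", "SI_P", "SI_H", "MCR"),
                             by = c("diet", "state")) {
  endpoints <- intersect(endpoints, names(results))
  if (!length(endpoints)) stop("no endpoint columns found")
  key <- interaction(results[by], drop = TRUE, sep = ":")
  rows <- list()
  for (g in levels(key)) {
    sub <- results[key == g, , drop = FALSE]
    n <- nrow(sub)
    for (ep in endpoints) {
      v <- sub[[ep]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, endpoint = ep, n = n, mean = mean(v),
        sem = if (n >= 2L) stats::sd(v) / sqrt(n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Two-sided pooled-variance (Student's) t test
#'
#' @param a,b numeric vectors, each with at least 2 observations (unpaired)
#'   or equal length (paired).
#' @param paired if TRUE, a one-sample t test on the differences a - b.
#' @return list with `t`, `df`, `p`, the group means and the pooled SD.
#'   Degenerate zero-variance inputs: equal means give t = 0, p = 1;
#'   unequal means give infinite t and p = 0.
#' @export
unpaired_t_test <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired) {
    if (length(a) != length(b)) stop("paired test needs equal lengths")
    d <- a - b
    n <- length(d)
    if (n < 2L) stop("need at least 2 pairs")
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      t <- mean(d) / (sd_d / sqrt(n))
    }
    df <- n - 1L
    return(list(t = t, df = df, p = .t_p(t, df),
                mean_a = mean(a), mean_b = mean(b), sd_pooled = sd_d))
  }
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  df <- na + nb - 2L
  num <- mean(a) - mean(b)
  if (sp2 == 0) {
    t <- if (num == 0) 0 else sign(num) * Inf
  } else {
    t <- num / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t = t, df = df, p = .t_p(t, df),
       mean_a = mean(a), mean_b = mean(b), sd_pooled = sqrt(sp2))
}

.t_p <- function(t, df) {
  if (!is.finite(t)) return(0)
  2 * stats::pt(-abs(t), df)
}

#' Two-way ANOVA (diet x anesthesia) with Tukey pairwise comparisons
#'
#' Fits the two-factor model with interaction and reports Type-II sums of
#' squares (main effects adjusted for each other but not for the
#' interaction), the standard default for unbalanced factorials such as a
#' 16/16/16/8 design; Type choice is exposed. Tukey HSD contrasts are
#' computed on the four cell means using the residual mean square of the
#' cell-means model. With an empty cell the interaction is dropped with a
#' warning.
#'
#' @param y numeric endpoint values.
#' @param diet,state factors (or coercible) of the same length as `y`.
#' @param ss_type 2 or 3 (passed to car::Anova).
#' @return list of class `anova_table`: `table` (rows diet, state,
#'   diet:state, Residuals with SS, df, F, p), `tukey` (data.frame of
#'   pairwise cell contrasts with adjusted p), `model` (the fitted lm).
#' @export
two_way_anova <- function(y, diet, state, ss_type = 2) {
  d <- data.frame(y = as.numeric(y), diet = factor(diet), state = factor(state))
  if (nlevels(d$diet) < 2L && nlevels(d$state) < 2L)
    stop("singular design: need at least two levels on one factor")
  tab_cells <- table(d$diet, d$state)
  has_empty <- any(tab_cells == 0)
  # endpoints live on very different scales (MCR ~ 1e-2, SS ~ 1e-8 would
  # trip absolute zero-variance checks); F and p are scale-invariant, so
  # fit on standardized values and restore the SS scale afterwards
  y_scale <- stats::sd(d$y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  d$y_std <- d$y / y_scale
  if (has_empty) {
    warning("empty diet x state cell: interaction dropped")
    fit <- stats::lm(y_std ~ diet + state, data = d)
  } else {
    if (any(tab_cells < 2))
      stop("need >= 2 observations per populated cell for the interaction term")
    fit <- stats::lm(y_std ~ diet * state, data = d)
  }
  ca <- car::Anova(fit, type = ss_type)
  tab <- data.frame(term = rownames(ca), SS = ca[["Sum Sq"]] * y_scale^2,
                    df = ca[["Df"]],
                    F = ca[["F value"]], p = ca[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  # Tukey on the four cell means, residual MS from the cell-means model
  d$cell <- interaction(d$diet, d$state, drop = TRUE, sep = ":")
  tk <- NULL
  if (nlevels(d$cell) >= 2L && all(table(d$cell) >= 2L)) {
    hsd <- stats::TukeyHSD(stats::aov(y ~ cell, data = d))$cell
    tk <- data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
                     lwr = hsd[, "lwr"], upr = hsd[, "upr"],
                     p_adj = hsd[, "p adj"], stringsAsFactors = FALSE,
                     row.names = NULL)
  }
  structure(list(table = tab, tukey = tk, model = fit, ss_type = ss_type),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (Type", x$ss_type, "SS)\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$tukey)) {
    cat("\nTukey pairwise comparisons (cell means):\n")
    print(x$tukey, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Conscious-to-anesthetized percent reductions by diet
#'
#' Group-mean SI in the conscious (reference) and anesthetized (test)
#' condition per diet, turned into [percent_reduction()] values for the
#' peripheral and hepatic indices.
#'
#' @param results per-animal results with columns diet, state, SI_P, SI_H.
#' @return data.frame with one row per diet: mean conscious / anesthetized
#'   SI_P and SI_H and their percent reductions.
#' @export
anesthesia_reductions <- function(results) {
  out <- list()
  for (dt in unique(results$diet)) {
    con <- results[results$diet == dt & results$state == "conscious", ]
    ane <- results[results$diet == dt & results$state == "anesthetized", ]
    if (!nrow(con) || !nrow(ane)) next
    out[[dt]] <- data.frame(
      diet = dt,
      SI_P_conscious = mean(con$SI_P), SI_P_anesthetized = mean(ane$SI_P),
      SI_H_conscious = mean(con$SI_H), SI_H_anesthetized = mean(ane$SI_H),
      reduction_SI_P = percent_reduction(mean(con$SI_P), mean(ane$SI_P)),
      reduction_SI_H = percent_reduction(mean(con$SI_H), mean(ane$SI_H)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
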
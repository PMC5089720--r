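test_that("group summaries give mean and SEM, with n = 1 undefined", {
  df <- data.frame(diet = c("lean", "lean", "lean", "fat_fed"),
                   state = "conscious",
                   SI_P = c(2, 4, 6, 5), MCR = c(1, 1, 1, 2))
  gs <- summarize_groups(df, endpoints = c("SI_P", "MCR"))
  lean_sip <- gs[gs$group == "lean:conscious" & gs$endpoint == "SI_P", ]
  expect_equal(lean_sip$mean, 4)
  expect_equal(lean_sip$sem, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(gs[gs$group == "lean:conscious" & gs$endpoint == "MCR", "sem"], 0)
  fat <- gs[gs$group == "fat_fed:conscious" & gs$endpoint == "SI_P", ]
  expect_equal(fat$n, 1L)
  expect_true(is.na(fat$sem))
})

test_that("SEM estimates are centred on sigma/sqrt(n)", {
  set.seed(8)
  sems <- replicate(600, stats::sd(rnorm(16, 5, 1)) / 4)
  expect_equal(mean(sems), 0.25, tolerance = 0.02)
})

test_that("pooled t test matches the closed form and the stats oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- unpaired_t_test(a, b)
  # pooled variance = 1, se = sqrt(2/3)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  # degenerate cases
  same <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  apart <- unpaired_t_test(c(2, 2, 2), c(3, 3, 3))
  expect_equal(apart$p, 0)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
})

test_that("paired t test operates on differences", {
  a <- c(5.1, 6.2, 5.8, 6.0); b <- c(4.9, 5.7, 5.6, 5.4)
  r <- unpaired_t_test(a, b, paired = TRUE)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
})

test_that("two-way ANOVA null and additive constructions behave as expected", {
  d <- expand.grid(diet = c("lean", "fat"), state = c("con", "ane"),
                   rep = 1:3)
  # equal cell means, symmetric within-cell spread: all effect F = 0
  y0 <- rep(c(-1, 0, 1), each = 4) + 10
  a0 <- two_way_anova(y0, d$diet, d$state)
  eff <- a0$table[a0$table$term != "Residuals", ]
  expect_true(all(abs(eff$F) < 1e-20))
  expect_true(all(eff$p > 0.999))
  # purely additive anesthesia shift: zero interaction SS, anesthesia F > 0
  shift <- ifelse(d$state == "ane", 2, 0)
  y1 <- y0 + shift
  a1 <- two_way_anova(y1, d$diet, d$state)
  tab <- a1$table
  expect_lt(tab$SS[tab$term == "diet:state"], 1e-18)
  expect_gt(tab$F[tab$term == "state"], 1)
})

test_that("balanced two-way ANOVA matches an explicit projection oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n_cell <- 4
    d <- expand.grid(diet = c("lean", "fat"), state = c("con", "ane"))
    d <- d[rep(seq_len(4), each = n_cell), ]
    y <- rnorm(nrow(d), mean = 5)
    # orthogonal contrast projections on a balanced design
    x1 <- ifelse(d$diet == "lean", 1, -1)
    x2 <- ifelse(d$state == "con", 1, -1)
    x3 <- x1 * x2
    proj_ss <- function(x) sum(x * y)^2 / sum(x * x)
    ss <- c(diet = proj_ss(x1), state = proj_ss(x2), inter = proj_ss(x3))
    ss_tot <- sum((y - mean(y))^2)
    ss_res <- ss_tot - sum(ss)
    df_res <- nrow(d) - 4
    f_ref <- (ss / 1) / (ss_res / df_res)
    p_ref <- stats::pf(f_ref, 1, df_res, lower.tail = FALSE)
    tab <- two_way_anova(y, d$diet, d$state)$table
    expect_equal(tab$SS[tab$term == "diet"], unname(ss["diet"]), tolerance = 1e-9)
    expect_equal(tab$SS[tab$term == "state"], unname(ss["state"]), tolerance = 1e-9)
    expect_equal(tab$SS[tab$term == "diet:state"], unname(ss["inter"]), tolerance = 1e-9)
    expect_equal(tab$F[tab$term == "diet"], unname(f_ref["diet"]), tolerance = 1e-9)
    expect_equal(tab$p[tab$term == "state"], unname(p_ref["state"]), tolerance = 1e-9)
    # SS decomposition closes on balanced designs
    expect_equal(sum(tab$SS), ss_tot, tolerance = 1e-9)
    # total df = N - 1
    expect_equal(sum(tab$df), nrow(d) - 1)
  }
})

test_that("unbalanced designs run with Type-II SS and full df accounting", {
  set.seed(23)
  d <- data.frame(diet = rep(c("lean", "lean", "fat", "fat"),
                             times = c(16, 16, 16, 8)),
                  state = rep(c("con", "ane", "con", "ane"),
                              times = c(16, 16, 16, 8)))
  y <- rnorm(nrow(d), 5) + ifelse(d$state == "ane", -1, 0)
  a <- two_way_anova(y, d$diet, d$state)
  expect_equal(sum(a$table$df), nrow(d) - 1)
  expect_true(all(a$table$SS >= 0))
  expect_gt(a$table$F[a$table$term == "state"], 1)
  expect_equal(nrow(a$tukey), choose(4, 2))
})

test_that("Tukey adjusted p-values are at least the unadjusted pairwise p", {
  set.seed(29)
  d <- expand.grid(diet = c("lean", "fat"), state = c("con", "ane"),
                   rep = 1:5)
  y <- rnorm(nrow(d), 5) + as.numeric(d$diet == "fat")
  a <- two_way_anova(y, d$diet, d$state)
  cell <- interaction(d$diet, d$state, sep = ":")
  fit <- stats::aov(y ~ cell)
  mse <- sum(stats::resid(fit)^2) / fit$df.residual
  for (i in seq_len(nrow(a$tukey))) {
    pair <- strsplit(a$tukey$comparison[i], "-", fixed = TRUE)[[1]]
    ya <- y[cell == pair[1]]; yb <- y[cell == pair[2]]
    tstat <- (mean(ya) - mean(yb)) /
      sqrt(mse * (1 / length(ya) + 1 / length(yb)))
    p_unadj <- 2 * stats::pt(-abs(tstat), fit$df.residual)
    expect_gte(a$tukey$p_adj[i] + 1e-12, p_unadj)
  }
})

test_that("empty cells drop the interaction with a warning", {
  d <- data.frame(diet = c(rep("lean", 6), rep("fat", 3)),
                  state = c(rep("con", 3), rep("ane", 3), rep("con", 3)))
  y <- rnorm(9)
  expect_warning(a <- two_way_anova(y, d$diet, d$state), "interaction dropped")
  expect_false("diet:state" %in% a$table$term)
})
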
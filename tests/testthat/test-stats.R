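test_that("block exclusion is strict at mean - 3 SD", {
  # solve for a block score that sits exactly at its own cohort cutoff
  # (many baseline blocks, so one low block cannot mask itself via the SD)
  base <- rep(c(72, 75, 78, 81, 84, 77, 79, 80, 76), 22)
  f <- function(x) {
    v <- c(base, x)
    x - (mean(v) - 3 * sd(v))
  }
  x_star <- uniroot(f, c(0, 70))$root
  blocks <- data.frame(task_family = "attention",
                       pct_correct = c(base, x_star))
  res <- exclude_outlier_blocks(blocks)
  expect_equal(nrow(res$excluded), 0)      # exactly at cutoff -> retained
  expect_equal(unname(res$cutoffs["attention"]), x_star, tolerance = 1e-6)
  blocks2 <- data.frame(task_family = "attention",
                        pct_correct = c(base, x_star - 1))
  res2 <- exclude_outlier_blocks(blocks2)
  # direct recomputation oracle
  cut2 <- mean(blocks2$pct_correct) - 3 * sd(blocks2$pct_correct)
  expect_equal(res2$excluded$pct_correct,
               blocks2$pct_correct[blocks2$pct_correct < cut2])
  # idempotence under the frozen first-pass cutoffs
  expect_true(all(res2$retained$pct_correct >= res2$cutoffs["attention"]))
})

test_that("a single gross outlier among 200 blocks is exactly removed", {
  set.seed(13)
  blocks <- data.frame(task_family = rep(c("attention", "nback"), each = 100),
                       pct_correct = c(rnorm(100, 85, 5), rnorm(100, 90, 4)))
  blocks$pct_correct[37] <- 5
  res <- exclude_outlier_blocks(blocks)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(res$excluded$pct_correct, 5)
  expect_identical(rownames(res$excluded), "37")
})

test_that("task scores follow the published trial-selection rules", {
  ev <- rbind(build_attention_schedule(1, seed = 1),
              build_nback_schedule(1, seed = 1))
  ev$correct[ev$task %in% c("attention", "nback")] <- TRUE
  sc <- compute_task_scores(ev)
  expect_equal(unname(sc), rep(100, 4))
  # 2-back block with 10 nonswitch (8 correct) and 6 switch trials -> 80
  fix <- data.frame(onset = seq(0, by = 3, length.out = 16), duration = 0.5,
                    task = "nback", condition = "nback2",
                    modality = "visual",
                    switch_flag = c(rep("nonswitch", 10),
                                    rep("post_switch", 3),
                                    rep("pre_switch", 3)),
                    congruent = NA, block_id = 1L, response_duration = 2.5,
                    correct = c(rep(TRUE, 8), rep(FALSE, 2), TRUE, FALSE,
                                TRUE, TRUE, TRUE, TRUE),
                    run = 1L)
  suppressWarnings(expect_warning(sc2 <- compute_task_scores(fix), "DivA"))
  expect_equal(unname(sc2["WM"]), 80)
  expect_equal(unname(sc2["ModSwi"]), 100 * 2 / 3)
  expect_true(is.na(sc2["DivA"]))
  # hand-count oracle on a 20-trial mixed fixture
  ev2 <- simulate_behavior(rbind(build_attention_schedule(1, seed = 2),
                                 build_nback_schedule(1, seed = 2)),
                           seed = 7, participant_shift = -20)
  tr <- ev2[ev2$task %in% c("attention", "nback"), ]
  sc3 <- compute_task_scores(ev2)
  oracle <- 100 * mean(tr$correct[tr$condition == "divided"])
  expect_equal(unname(sc3["DivA"]), oracle)
  oracle_ms <- 100 * mean(tr$correct[tr$condition %in% c("nback1", "nback2") &
                                       tr$switch_flag == "post_switch"])
  expect_equal(unname(sc3["ModSwi"]), oracle_ms)
})

test_that("partial correlation matches the recursive formula", {
  set.seed(14)
  x <- rnorm(60); z <- rnorm(60); y <- 0.4 * x - 0.5 * z + rnorm(60)
  pc <- partial_correlation(x, y, data.frame(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(pc$r, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-10)
  expect_equal(pc$df, 57)
  expect_equal(partial_correlation(x, y)$r, cor(x, y))
  # constant covariate degrades to the plain correlation
  pc_const <- partial_correlation(x, y, data.frame(c = rep(2, 60)))
  expect_equal(pc_const$r, cor(x, y), tolerance = 1e-12)
  # categorical covariate is dummy coded
  g <- rep(c("a", "b", "c"), 20)
  pc_cat <- partial_correlation(x, y, data.frame(g = g))
  expect_equal(pc_cat$df, 60 - 2 - 2)
})

test_that("repeated-measures ANOVA matches a hand sums-of-squares oracle", {
  set.seed(15)
  n <- 6; a <- 3
  Y <- matrix(rnorm(n * a, 10, 2), n)
  long <- data.frame(id = rep(1:n, a), task = rep(letters[1:a], each = n),
                     score = as.vector(Y))
  an <- rm_ancova(long, "score", "task", "id")
  gm <- mean(Y)
  ss_subj <- a * sum((rowMeans(Y) - gm)^2)
  ss_task <- n * sum((colMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_subj - ss_task
  F_or <- (ss_task / (a - 1)) / (ss_err / ((a - 1) * (n - 1)))
  row <- an$effects[an$effects$term == "task", ]
  expect_equal(row$F, F_or, tolerance = 1e-8)
  expect_equal(row$ss, ss_task, tolerance = 1e-8)
  expect_equal(row$eta_sq, ss_task / ss_tot, tolerance = 1e-10)
  expect_equal(an$ss_total, ss_tot)
})

test_that("Greenhouse-Geisser epsilon is 1 under compound symmetry", {
  set.seed(16)
  a <- 4; n <- 40
  S_cs <- 3 * diag(a) + 2   # compound-symmetric target covariance
  X0 <- scale(matrix(rnorm(n * a), n), scale = FALSE)
  W <- X0 %*% solve(chol(crossprod(X0) / (n - 1))) %*% chol(S_cs)
  long <- data.frame(id = rep(1:n, a), task = rep(letters[1:a], each = n),
                     score = as.vector(W))
  an <- rm_ancova(long, "score", "task", "id")
  expect_equal(an$epsilon, 1, tolerance = 1e-8)
  # two within levels force epsilon = 1 exactly
  long2 <- data.frame(id = rep(1:10, 2), task = rep(c("a", "b"), each = 10),
                      score = rnorm(20))
  expect_equal(rm_ancova(long2, "score", "task", "id")$epsilon, 1)
  # epsilon lower bound 1/(a-1)
  expect_gte(an$epsilon, 1 / (a - 1))
})

test_that("ANOVA F is invariant to affine response rescaling", {
  set.seed(17)
  long <- data.frame(id = rep(1:12, 3), task = rep(letters[1:3], each = 12),
                     score = rnorm(36, 50, 8),
                     grp = rep(rep(c("x", "y"), 6), 3))
  a1 <- rm_ancova(long, "score", "task", "id", between = "grp")
  long$score2 <- 4 * long$score - 100
  a2 <- rm_ancova(long, "score2", "task", "id", between = "grp")
  expect_equal(a1$effects$F, a2$effects$F, tolerance = 1e-10)
  expect_equal(a1$effects$eta_sq[a1$effects$term == "task:grp"],
               a2$effects$eta_sq[a2$effects$term == "task:grp"],
               tolerance = 1e-10)
})

test_that("missing scores drop participants listwise with a message", {
  long <- data.frame(id = rep(1:8, 4),
                     task = rep(letters[1:4], each = 8),
                     score = rnorm(32))
  long$score[long$id == 3 & long$task == "b"] <- NA
  expect_message(an <- rm_ancova(long, "score", "task", "id"), "dropping 1")
  expect_equal(an$n, 7)
  expect_equal(an$dropped, 3)
})

test_that("two-way ANOVA matches anova() on balanced data and sums eta^2", {
  set.seed(18)
  df <- expand.grid(f1 = c("a", "b", "c"), f2 = c("u", "v"), repn = 1:8)
  df$y <- rnorm(48) + 2 * (df$f1 == "a")
  ua <- univariate_anova(df, "y", c("f1", "f2"))
  ao <- anova(lm(y ~ f1 * f2, df))   # Type I == Type III when balanced
  expect_equal(ua$effects$ss, ao$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_lte(sum(ua$effects$eta_sq), 1)
  # identical groups -> F = 0, p = 1
  df2 <- expand.grid(f1 = c("a", "b"), f2 = c("u", "v"), repn = 1:5)
  df2$y <- rep(c(1, 2, 3, 4, 5), each = 4)
  expect_true(all(univariate_anova(df2, "y", c("f1", "f2"))$effects$p > 0.999))
})

test_that("planted cohort shifts in distances are detected with high power", {
  set.seed(19)
  hits <- 0
  n_reps <- 60
  for (r in seq_len(n_reps)) {
    df <- data.frame(cohort = rep(c("m", "l", "y"), each = 378),
                     type = rep(rep(c("wl", "wr", "ih"), length.out = 378), 3))
    shift <- c(m = 0.12, l = 0.05, y = 0)[df$cohort]
    df$distance <- 0.5 + shift + rnorm(nrow(df), 0, 0.25)
    ua <- univariate_anova(df, "distance", c("cohort", "type"))
    hits <- hits + (ua$effects$p[ua$effects$term == "cohort"] < 0.05)
  }
  expect_gte(hits / n_reps, 0.9)
})

test_that("Mauchly's test is reported and gates the corrected p", {
  set.seed(20)
  n <- 30; a <- 3
  base <- matrix(rnorm(n * a), n)
  base[, 3] <- base[, 1] + rnorm(n, 0, 0.05)  # strong sphericity violation
  long <- data.frame(id = rep(1:n, a), task = rep(letters[1:a], each = n),
                     score = as.vector(base))
  an <- rm_ancova(long, "score", "task", "id")
  expect_lt(an$mauchly$p, 0.05)
  row <- an$effects[an$effects$term == "task", ]
  expect_equal(row$p_used, row$p_gg)
  expect_lt(an$epsilon, 1)
})
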
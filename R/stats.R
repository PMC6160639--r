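# Behavioral scoring, outlier-block exclusion, partial correlations, and
# the ANOVA/ANCOVA machinery (Type-III sums of squares, Greenhouse-Geisser
# epsilon, Mauchly's test, eta squared, Bonferroni post hocs).
#
# No Type-III ANOVA provider ships with the target environment, so the
# split-plot decomposition is implemented directly via orthonormal
# within-subject contrasts and model-comparison sums of squares; tests
# check it against hand sums-of-squares oracles.

#' Per-block percent-correct scores
#'
#' @param events scored `event_table`(s) for one participant (rbind of
#'   runs), `correct` filled
#' @return data frame: run, block_id, condition, task_family, n_trials,
#'   pct_correct
#' @export
block_scores <- function(events) {
  tr <- trial_rows(events)
  tr <- tr[!is.na(tr$correct), , drop = FALSE]
  if (nrow(tr) == 0) return(data.frame())
  key <- paste(tr$run, tr$block_id, sep = "\r")
  first <- !duplicated(key)
  n_tr <- as.vector(rowsum(rep(1L, nrow(tr)), key))
  n_ok <- as.vector(rowsum(as.numeric(tr$correct), key))
  ord <- sort(unique(key))
  f_ord <- match(ord, key) # rowsum sorts by key; map back to first rows
  agg <- data.frame(run = tr$run[f_ord], block_id = tr$block_id[f_ord],
                    condition = tr$condition[f_ord],
                    task_family = ifelse(tr$task[f_ord] == "nback",
                                         "nback", "attention"),
                    n_trials = n_tr, pct_correct = 100 * n_ok / n_tr,
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$run, agg$block_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Remove blocks far below average performance
#'
#' Within each task family the block mean and SD of percent correct are
#' computed across all supplied blocks (all participants pooled); blocks
#' strictly below mean - 3 SD are removed. A block exactly at the cutoff is
#' retained. Cutoffs are frozen from this first pass, making the rule
#' idempotent on the retained set.
#'
#' @param blocks data frame with `task_family` and `pct_correct` columns
#'   (e.g. rbind of [block_scores()] over participants)
#' @param n_sd number of SDs below the mean (default 3)
#' @return list: `retained`, `excluded` (data frames) and `cutoffs`
#'   (named per family)
#' @export
exclude_outlier_blocks <- function(blocks, n_sd = 3) {
  fams <- unique(blocks$task_family)
  cutoffs <- vapply(fams, function(f) {
    x <- blocks$pct_correct[blocks$task_family == f]
    mean(x) - n_sd * stats::sd(x)
  }, numeric(1))
  names(cutoffs) <- fams
  drop <- blocks$pct_correct < cutoffs[blocks$task_family]
  drop[is.na(drop)] <- FALSE
  list(retained = blocks[!drop, , drop = FALSE],
       excluded = blocks[drop, , drop = FALSE],
       cutoffs = cutoffs)
}

#' Executive task-type scores for one participant
#'
#' DivA: percent correct in divided-attention blocks. DistrA: pooled over
#' the three distracted conditions. WM: 2-back nonswitch trials only.
#' ModSwi: post-switch trials pooled over the 1- and 2-back levels.
#'
#' @param events scored `event_table`(s) for one participant
#' @param retained_blocks optional data frame with `run` and `block_id` of
#'   blocks to keep (from [exclude_outlier_blocks()]); default keeps all
#' @return named numeric vector (DivA, DistrA, WM, ModSwi); a score with no
#'   eligible trials is `NA` with a warning
#' @export
compute_task_scores <- function(events, retained_blocks = NULL) {
  tr <- trial_rows(events)
  tr <- tr[!is.na(tr$correct), , drop = FALSE]
  if (!is.null(retained_blocks)) {
    keep_key <- paste(retained_blocks$run, retained_blocks$block_id)
    tr <- tr[paste(tr$run, tr$block_id) %in% keep_key, , drop = FALSE]
  }
  pick <- list(
    DivA = tr$condition == "divided",
    DistrA = tr$condition %in% DISTRACTED_CONDITIONS,
    WM = tr$condition == "nback2" & tr$switch_flag == "nonswitch",
    ModSwi = tr$condition %in% c("nback1", "nback2") &
      tr$switch_flag == "post_switch")
  out <- vapply(names(pick), function(nm) {
    sel <- pick[[nm]]
    if (!any(sel)) {
      warnf("no eligible trials for %s; score is NA", nm)
      return(NA_real_)
    }
    100 * mean(tr$correct[sel])
  }, numeric(1))
  out
}

#' Partial correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the
#' covariates (plus intercept); categorical covariates are dummy coded.
#' With no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors
#' @param covariates optional data frame / matrix of covariates
#' @return list: `r`, `p` (two-sided t test), `df`
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    X <- stats::model.matrix(~ ., data = cv)
    qx <- qr(X)
    k <- qx$rank - 1L # covariate columns beyond the intercept
    x <- x - qr.fitted(qx, x)
    y <- y - qr.fitted(qx, y)
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

# ---- Type-III machinery ------------------------------------------------

# model matrix with sum-to-zero factor coding and centred covariates,
# plus the term assignment needed for Type-III model comparisons
sum_coded_design <- function(df, formula) {
  vars <- all.vars(formula)
  for (v in vars) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  contr <- lapply(df[vars], function(col)
    if (is.factor(col)) "contr.sum" else NULL)
  contr <- contr[!vapply(contr, is.null, logical(1))]
  for (v in vars) if (is.numeric(df[[v]])) df[[v]] <- df[[v]] - mean(df[[v]])
  mm <- stats::model.matrix(formula, data = df, contrasts.arg = contr)
  list(X = mm, assign = attr(mm, "assign"),
       terms = attr(stats::terms(formula), "term.labels"))
}

rss_of <- function(X, y) {
  if (ncol(X) == 0) return(sum((y)^2))
  sum(qr.resid(qr(X), y)^2)
}

# Type-III SS per term (and for the intercept) via model comparison
type3_ss <- function(X, assign, terms, y) {
  full <- rss_of(X, y)
  out <- lapply(c(0L, seq_along(terms)), function(tt) {
    keep <- assign != tt
    list(term = if (tt == 0L) "(Intercept)" else terms[tt],
         ss = rss_of(X[, keep, drop = FALSE], y) - full,
         df = sum(assign == tt))
  })
  names(out) <- vapply(out, `[[`, character(1), "term")
  attr(out, "rss") <- full
  out
}

orthonormal_within_contrasts <- function(a) {
  C <- stats::contr.helmert(a)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Repeated-measures ANCOVA (split-plot, Type III)
#'
#' Classical univariate mixed ANOVA with one within-participant factor,
#' optional between-participant factors (full factorial), and an optional
#' continuous covariate. Reports Type-III F tests, Greenhouse-Geisser
#' epsilon (applied per Mauchly's test), eta squared against the total sum
#' of squares, and Bonferroni post hoc comparisons.
#'
#' @param data long-format data frame
#' @param dv name of the response column
#' @param within name of the within-participant factor column
#' @param id name of the participant identifier column
#' @param between character vector of between-participant factor columns
#' @param covariate optional continuous covariate column (participant
#'   level)
#' @param alpha significance level for Mauchly gating and post hocs
#' @return an `anova_result` list: `effects` data frame (term, ss, df1,
#'   df2, F, p, p_gg, p_used, epsilon, eta_sq), `mauchly`, `posthoc`,
#'   `dropped`
#' @export
rm_ancova <- function(data, dv, within, id, between = character(0),
                      covariate = NULL, alpha = 0.05) {
  data <- as.data.frame(data)
  data[[within]] <- factor(data[[within]])
  lev <- levels(data[[within]])
  a <- length(lev)
  ids <- unique(data[[id]])
  Y <- matrix(NA_real_, length(ids), a, dimnames = list(NULL, lev))
  Y[cbind(match(data[[id]], ids), match(as.character(data[[within]]), lev))] <-
    data[[dv]]
  wide <- data[!duplicated(data[[id]]), c(id, between, covariate),
               drop = FALSE]
  wide <- wide[match(ids, wide[[id]]), , drop = FALSE]
  ok <- stats::complete.cases(Y)
  dropped <- ids[!ok]
  if (length(dropped) > 0)
    message(sprintf("rm_ancova: dropping %d participant(s) with missing scores",
                    length(dropped)))
  wide <- wide[ok, , drop = FALSE]
  Y <- Y[ok, , drop = FALSE]
  n <- nrow(wide)
  for (b in between) wide[[b]] <- factor(wide[[b]])
  if (n < 2) stopf("need at least 2 complete participants")
  if (length(between) > 0) {
    cells <- interaction(wide[between], drop = FALSE)
    if (any(table(cells) == 0))
      stopf("empty between-participant cell(s): %s",
            paste(names(table(cells))[table(cells) == 0], collapse = ", "))
  }
  rhs <- c(if (length(between) > 0)
    paste(between, collapse = " * "), covariate)
  form <- stats::as.formula(paste("~", if (length(rhs) > 0)
    paste(rhs, collapse = " + ") else "1"))
  des <- sum_coded_design(wide, form)
  B <- des$X
  p_b <- qr(B)$rank
  if (p_b < ncol(B)) stopf("between-participant design is rank deficient")

  ss_total <- sum((Y - mean(Y))^2)
  eff <- list()
  add_eff <- function(term, ss, df1, ss_err, df2, within_part, epsilon = NA) {
    F <- (ss / df1) / (ss_err / df2)
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    p_gg <- if (within_part && !is.na(epsilon))
      stats::pf(F, df1 * epsilon, df2 * epsilon, lower.tail = FALSE) else NA
    eff[[length(eff) + 1]] <<- data.frame(
      term = term, ss = ss, df1 = df1, df2 = df2, F = F, p = p,
      p_gg = p_gg, epsilon = epsilon, eta_sq = ss / ss_total,
      stringsAsFactors = FALSE)
  }

  # between-participant part: subject means, SS scaled by a
  P <- rowMeans(Y)
  t3b <- type3_ss(B, des$assign, des$terms, P)
  rss_b <- attr(t3b, "rss")
  df_err_b <- n - p_b
  for (tt in des$terms)
    add_eff(tt, a * t3b[[tt]]$ss, t3b[[tt]]$df, a * rss_b, df_err_b, FALSE)

  # within-participant part on orthonormal contrasts
  M <- orthonormal_within_contrasts(a)
  Z <- Y %*% M
  ss_int <- 0; ss_terms <- stats::setNames(rep(0, length(des$terms)), des$terms)
  rss_w <- 0
  E <- matrix(0, n, a - 1)
  for (cidx in seq_len(a - 1)) {
    z <- Z[, cidx]
    t3 <- type3_ss(B, des$assign, des$terms, z)
    ss_int <- ss_int + t3[["(Intercept)"]]$ss
    for (tt in des$terms) ss_terms[tt] <- ss_terms[tt] + t3[[tt]]$ss
    rss_w <- rss_w + attr(t3, "rss")
    E[, cidx] <- qr.resid(qr(B), z)
  }
  S <- crossprod(E) / (n - p_b)
  epsilon <- if (a > 1) sum(diag(S))^2 / ((a - 1) * sum(S * S)) else 1
  df_err_w <- (a - 1) * (n - p_b)
  add_eff(within, ss_int, a - 1, rss_w, df_err_w, TRUE, epsilon)
  for (tt in des$terms)
    add_eff(paste(within, tt, sep = ":"), ss_terms[tt],
            (a - 1) * t3b[[tt]]$df, rss_w, df_err_w, TRUE, epsilon)

  mauchly <- mauchly_test(S, a, n - p_b)
  effects <- do.call(rbind, eff)
  effects$p_used <- ifelse(!is.na(effects$p_gg) & mauchly$significant,
                           effects$p_gg, effects$p)

  posthoc <- list()
  # within post hoc: paired t tests, Bonferroni over level pairs
  ncmp <- choose(a, 2)
  ph <- list()
  for (i in seq_len(a - 1)) for (j in (i + 1):a) {
    d <- Y[, i] - Y[, j]
    tt <- stats::t.test(d)
    ph[[length(ph) + 1]] <- data.frame(
      pair = paste(lev[i], lev[j], sep = " - "),
      mean_diff = mean(d),
      p_bonferroni = min(1, tt$p.value * ncmp), stringsAsFactors = FALSE)
  }
  posthoc[[within]] <- do.call(rbind, ph)
  for (b in between) {
    lv <- levels(wide[[b]]); nb <- choose(length(lv), 2)
    ph <- list()
    for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
      xi <- P[wide[[b]] == lv[i]]; xj <- P[wide[[b]] == lv[j]]
      tt <- stats::t.test(xi, xj)
      ph[[length(ph) + 1]] <- data.frame(
        pair = paste(lv[i], lv[j], sep = " - "),
        mean_diff = mean(xi) - mean(xj),
        p_bonferroni = min(1, tt$p.value * nb), stringsAsFactors = FALSE)
    }
    posthoc[[b]] <- do.call(rbind, ph)
  }

  structure(list(effects = effects, epsilon = epsilon, mauchly = mauchly,
                 posthoc = posthoc, dropped = dropped, n = n,
                 ss_total = ss_total),
            class = "anova_result")
}

# Mauchly's sphericity test on the pooled contrast covariance
mauchly_test <- function(S, a, n_resid, alpha = 0.05) {
  p <- a - 1
  if (p < 2) return(list(W = NA, chisq = NA, df = NA, p = NA,
                         significant = FALSE))
  W <- det(S) / (sum(diag(S)) / p)^p
  dfm <- p * (p + 1) / 2 - 1
  mult <- n_resid - (2 * p^2 + p + 2) / (6 * p)
  chisq <- -mult * log(max(W, .Machine$double.xmin))
  pval <- stats::pchisq(chisq, dfm, lower.tail = FALSE)
  list(W = W, chisq = chisq, df = dfm, p = pval,
       significant = is.finite(pval) && pval < alpha)
}

#' Two-way fixed-effects ANOVA (Type III)
#'
#' Full-factorial two-way ANOVA with interaction, Type-III sums of
#' squares, eta squared, and Bonferroni pairwise comparisons on each main
#' effect (pooled-error t tests).
#'
#' @param data data frame
#' @param dv response column name
#' @param factors character vector of exactly two factor column names
#' @param alpha significance level used only to annotate post hocs
#' @return an `anova_result` list: `effects`, `posthoc`
#' @export
univariate_anova <- function(data, dv, factors, alpha = 0.05) {
  stopifnot(length(factors) == 2)
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  form <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  des <- sum_coded_design(data, form)
  y <- data[[dv]]
  t3 <- type3_ss(des$X, des$assign, des$terms, y)
  rss <- attr(t3, "rss")
  df_err <- length(y) - qr(des$X)$rank
  ss_total <- sum((y - mean(y))^2)
  effects <- do.call(rbind, lapply(des$terms, function(tt) {
    ss <- t3[[tt]]$ss; df1 <- t3[[tt]]$df
    F <- (ss / df1) / (rss / df_err)
    data.frame(term = tt, ss = ss, df1 = df1, df2 = df_err, F = F,
               p = stats::pf(F, df1, df_err, lower.tail = FALSE),
               eta_sq = ss / ss_total, stringsAsFactors = FALSE)
  }))
  mse <- rss / df_err
  posthoc <- list()
  for (f in factors) {
    lv <- levels(data[[f]]); ncmp <- choose(length(lv), 2)
    ph <- list()
    for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
      xi <- y[data[[f]] == lv[i]]; xj <- y[data[[f]] == lv[j]]
      se <- sqrt(mse * (1 / length(xi) + 1 / length(xj)))
      tval <- (mean(xi) - mean(xj)) / se
      ph[[length(ph) + 1]] <- data.frame(
        pair = paste(lv[i], lv[j], sep = " - "),
        mean_diff = mean(xi) - mean(xj),
        p_bonferroni = min(1, 2 * stats::pt(-abs(tval), df_err) * ncmp),
        stringsAsFactors = FALSE)
    }
    posthoc[[f]] <- do.call(rbind, ph)
  }
  structure(list(effects = effects, posthoc = posthoc, rss = rss,
                 df_err = df_err, ss_total = ss_total),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$effects, digits = 4)
  invisible(x)
}
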
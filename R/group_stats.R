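# Group comparison: the two analysis arms.
#
# Arm 1 (partial volume): MANOVA of the per-region feature triple
# (mu_gm, mu_wm, C_GM/C_WM) on group with age and sex as covariates,
# followed by two-tailed permutation two-sample t-tests on each component
# to attribute any multivariate difference.
# Arm 2 (global averaging): a two-sample t-test (linear model with
# covariates) on the region-mean T1.
# Multiplicity is corrected by Bonferroni across regions for the MANOVA
# and global arms, and across the three components within a region
# (Bonferroni or max-statistic permutation FWE) for the component arm.

check_groups <- function(group, min_n = 2) {
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("exactly two groups are required", call. = FALSE)
  n <- table(group)
  if (any(n < min_n))
    stop("each group needs at least ", min_n, " subjects (got ",
         paste(n, collapse = " and "), ")", call. = FALSE)
  group
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != n) stop("covariates do not match the data", call. = FALSE)
  X
}

# residualize y (vector or matrix) on covariates incl. intercept
residualize <- function(y, covariates) {
  if (is.null(covariates)) return(scale(as.matrix(y), scale = FALSE))
  X <- covariate_matrix(covariates, NROW(y))
  stats::lm.fit(X, as.matrix(y))$residuals
}

pooled_t <- function(x, group) {
  g <- split(x, group)
  n1 <- length(g[[1]]); n2 <- length(g[[2]])
  sp2 <- (sum((g[[1]] - mean(g[[1]]))^2) + sum((g[[2]] - mean(g[[2]]))^2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) return(0)
  (mean(g[[1]]) - mean(g[[2]])) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' MANOVA group test on the partial-volume feature triple
#'
#' Fits a multivariate linear model of the features on the covariates and
#' the group factor (group entered last, so its term is
#' covariate-adjusted) and reports Pillai's trace with its standard F
#' approximation. With a single feature this reduces to the univariate
#' F test of the group term, whose p-value equals the pooled two-sample
#' t-test p when no covariates are present.
#'
#' @param features Numeric matrix or data.frame, one row per subject, one
#'   column per feature (no missing values).
#' @param group Two-level factor (or coercible), at least 3 per group.
#' @param covariates Optional data.frame of covariates (e.g. age, sex).
#' @return A list with `statistic` (Pillai's trace), `approx_f`, `df`,
#'   `p_raw` and `n_per_group`.
#' @export
manova_group_test <- function(features, group, covariates = NULL) {
  Y <- as.matrix(features)
  if (anyNA(Y)) stop("missing feature values", call. = FALSE)
  group <- check_groups(group, min_n = 3)
  n <- nrow(Y)
  dat <- data.frame(.group = group)
  rhs <- ".group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(covariates, dat)
    rhs <- paste(c(names(covariates), ".group"), collapse = " + ")
  }
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), dat)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (a covariate is collinear with the group ",
         "or with another covariate)", call. = FALSE)
  if (n <= ncol(X) + ncol(Y) - 1)
    stop("fewer subjects than model parameters", call. = FALSE)
  if (ncol(Y) >= 2) {
    fit <- stats::manova(stats::as.formula(paste("Y ~", rhs)), data = dat)
    st <- summary(fit, test = "Pillai")$stats
    row <- st[".group", ]
    out <- list(statistic = unname(row["Pillai"]),
                approx_f = unname(row["approx F"]),
                df = unname(c(row["num Df"], row["den Df"])),
                p_raw = unname(row["Pr(>F)"]))
  } else {
    y <- Y[, 1]
    full <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
    red <- if (is.null(covariates)) stats::lm(y ~ 1, data = dat)
           else stats::lm(stats::as.formula(
             paste("y ~", paste(names(covariates), collapse = " + "))), data = dat)
    an <- stats::anova(red, full)
    f <- an$F[2]; df1 <- an$Df[2]; df2 <- an$Res.Df[2]
    out <- list(statistic = unname(df1 * f / (df2 + df1 * f)),  # Pillai analogue
                approx_f = unname(f),
                df = c(df1, df2),
                p_raw = unname(an$`Pr(>F)`[2]))
  }
  out$n_per_group <- as.vector(table(group))
  out
}

# |t| statistics for many permutations at once, from group-1 sums.
# r: residualized feature; perm_idx: n1 x B matrix of group-1 row indices.
perm_abs_t <- function(r, n1, n2, perm_idx) {
  n <- n1 + n2
  S <- sum(r); SS <- sum(r * r)
  s1 <- colSums(matrix(r[perm_idx], nrow = n1))
  m1 <- s1 / n1; m2 <- (S - s1) / n2
  sp2 <- (SS - n1 * m1^2 - n2 * m2^2) / (n - 2)
  sp2[sp2 < 0] <- 0
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[!is.finite(t)] <- 0
  abs(t)
}

# All or sampled group-1 index sets. Exhaustive when the number of splits
# is at most `exhaustive_limit`.
make_perm_sets <- function(n, n1, n_perm, exhaustive_limit = 20000) {
  n_splits <- choose(n, n1)
  if (n_splits <= exhaustive_limit) {
    list(idx = utils::combn(n, n1), exhaustive = TRUE)
  } else {
    list(idx = replicate(n_perm, sample.int(n, n1)), exhaustive = FALSE)
  }
}

#' Two-tailed permutation two-sample t-test with covariate adjustment
#'
#' Covariates are regressed out of the feature first and the group labels
#' of the residuals are permuted (a Freedman-Lane-style residual
#' permutation scheme). The p-value is
#' `(1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm)` for sampled permutations; when
#' the number of distinct label splits is at most `exhaustive_limit` the
#' full enumeration is used instead and the p-value is the exact
#' proportion of splits with `|t*| >= |t_obs|`.
#'
#' @param x Numeric feature vector, one value per subject.
#' @param group Two-level factor (or coercible), at least 2 per group.
#' @param covariates Optional data.frame of covariates.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Seed for the permutation draw; required for reproducibility
#'   when permutations are sampled.
#' @param exhaustive_limit Switch to full enumeration when the number of
#'   group-label splits is at most this (default 20000).
#' @return A list with `statistic` (observed t on residuals), `p_raw`,
#'   `exhaustive`, `n_perm_used` and `n_per_group`.
#' @export
permutation_component_test <- function(x, group, covariates = NULL,
                                       n_perm = 10000, seed = NULL,
                                       exhaustive_limit = 20000) {
  group <- check_groups(group, min_n = 2)
  r <- as.vector(residualize(x, covariates))
  n1 <- sum(group == levels(group)[1]); n2 <- length(r) - n1
  if (stats::var(r) <= .Machine$double.eps * mean(r^2 + 1)) {
    warning("constant feature: permutation t-test is degenerate, p = 1",
            call. = FALSE)
    return(list(statistic = 0, p_raw = 1, exhaustive = TRUE,
                n_perm_used = 0L, n_per_group = c(n1, n2)))
  }
  # order residuals so that group 1 comes first; |t| only depends on the set
  r <- c(r[group == levels(group)[1]], r[group == levels(group)[2]])
  t_obs <- abs(pooled_t(r, rep(c(1, 2), c(n1, n2))))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  ps <- make_perm_sets(n1 + n2, n1, n_perm, exhaustive_limit)
  t_perm <- perm_abs_t(r, n1, n2, ps$idx)
  if (ps$exhaustive) {
    p <- mean(t_perm >= t_obs - 1e-12)
    B <- ncol(ps$idx)
  } else {
    p <- (1 + sum(t_perm >= t_obs - 1e-12)) / (1 + n_perm)
    B <- n_perm
  }
  list(statistic = t_obs, p_raw = p, exhaustive = ps$exhaustive,
       n_perm_used = B, n_per_group = c(n1, n2))
}

#' Two-sample test of region-mean T1 with covariates (global arm)
#'
#' A linear model of mean T1 on covariates plus group; reports the
#' two-tailed p of the group coefficient. Without covariates this is
#' exactly the classical pooled-variance two-sample t-test.
#'
#' @inheritParams permutation_component_test
#' @return A list with `statistic` (t of the group coefficient), `df`,
#'   `p_raw` and `n_per_group`.
#' @export
global_mean_test <- function(x, group, covariates = NULL) {
  group <- check_groups(group, min_n = 3)
  dat <- data.frame(.y = x, .group = group)
  rhs <- ".group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(names(covariates), ".group"), collapse = " + ")
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design (a covariate is collinear with the group)",
         call. = FALSE)
  co <- summary(fit)$coefficients
  row <- grep("^\\.group", rownames(co))
  list(statistic = unname(co[row, "t value"]),
       df = fit$df.residual,
       p_raw = unname(co[row, "Pr(>|t|)"]),
       n_per_group = as.vector(table(group)))
}

#' Multiple-comparison correction
#'
#' `bonferroni`: `p_corr = min(1, m * p_raw)` with `m` the family size.
#' `max_stat_fwe`: single-step max-statistic permutation correction - each
#' observed |t| is compared against the permutation distribution of the
#' maximum |t| across the family; requires the per-feature permutation
#' statistics (`perm_stats`) and observed statistics (`stat_obs`) from a
#' shared set of permutations.
#'
#' @param p_raw Numeric vector of raw p-values (the family).
#' @param method `"bonferroni"` or `"max_stat_fwe"`.
#' @param perm_stats For `max_stat_fwe`: matrix of permutation |t| values,
#'   one column per family member, one row per permutation.
#' @param stat_obs For `max_stat_fwe`: observed |t| per family member.
#' @param exhaustive For `max_stat_fwe`: whether `perm_stats` enumerates
#'   all splits (exact proportion) or samples them (add-one estimate).
#' @return Numeric vector of corrected p-values, each `>= p_raw` and `<= 1`.
#' @export
correct_multiplicity <- function(p_raw, method = c("bonferroni", "max_stat_fwe"),
                                 perm_stats = NULL, stat_obs = NULL,
                                 exhaustive = FALSE) {
  if (length(p_raw) == 0) stop("empty p-value family", call. = FALSE)
  method <- match.arg(method)
  if (method == "bonferroni") {
    return(pmin(1, length(p_raw) * p_raw))
  }
  if (is.null(perm_stats) || is.null(stat_obs))
    stop("max_stat_fwe needs perm_stats and stat_obs", call. = FALSE)
  mx <- apply(as.matrix(perm_stats), 1, max)
  p_fwe <- vapply(stat_obs, function(t0) {
    if (exhaustive) mean(mx >= t0 - 1e-12)
    else (1 + sum(mx >= t0 - 1e-12)) / (1 + length(mx))
  }, numeric(1))
  pmax(pmin(p_fwe, 1), p_raw)
}

#' Run both comparison arms over all regions
#'
#' For each region: one MANOVA row on the feature triple, three
#' permutation component rows (sharing one permutation set, so the
#' max-statistic correction is available), and one global-mean row.
#' Corrections: the regions form the family for the MANOVA and global
#' arms (Bonferroni); the three components within a region form the family
#' for the component arm (method set by `config$stats$correction`).
#' Subjects with missing features are dropped pairwise per region with a
#' logged count. Deterministic given `config$stats$seed`.
#'
#' @param features Feature table from [extract_cohort_features] (or
#'   [read_cohort_table]-compatible CSV read), one row per subject.
#' @param cohort Cohort table with `subject_id`, `group`, `age`, `sex`.
#' @param config Run configuration (see [default_run_config]).
#' @return A data.frame with one row per region x test: columns `region`,
#'   `arm` (`pv_manova`, `pv_component`, `global_mean`), `feature`,
#'   `statistic`, `p_raw`, `p_corrected`, `correction_method`, `n_hc`,
#'   `n_patient`.
#' @export
run_comparison <- function(features, cohort, config = default_run_config()) {
  regions <- config$regions
  n_perm <- config$stats$n_perm
  correction <- config$stats$correction
  seed <- config$stats$seed

  extra <- setdiff(features$subject_id, cohort$subject_id)
  if (length(extra))
    stop("subjects in features but not in cohort: ",
         paste(extra, collapse = ", "), call. = FALSE)
  dat <- merge(cohort[, c("subject_id", "group", "age", "sex")], features,
               by = "subject_id")
  dat$group <- factor(normalize_group(dat$group), levels = c("HC", "PATIENT"))
  covars <- function(d) data.frame(age = d$age, sex = factor(d$sex))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  rows <- list()
  manova_p <- c(); global_p <- c()
  for (r in regions) {
    triple_cols <- paste0(r, c("_mu_gm", "_mu_wm", "_ratio"))
    mean_col <- paste0(r, "_mean_t1")
    if (!all(c(triple_cols, mean_col) %in% names(dat)))
      stop("region '", r, "' absent from the feature table", call. = FALSE)
    keep <- stats::complete.cases(dat[, c(triple_cols, mean_col)])
    if (sum(!keep) > 0)
      message("region ", r, ": dropping ", sum(!keep),
              " subject(s) with missing features")
    d <- dat[keep, , drop = FALSE]
    g <- droplevels(d$group)
    n_hc <- sum(g == "HC"); n_pat <- sum(g == "PATIENT")

    mv <- manova_group_test(d[, triple_cols], g, covars(d))
    rows[[length(rows) + 1]] <- data.frame(
      region = r, arm = "pv_manova", feature = NA_character_,
      statistic = mv$statistic, p_raw = mv$p_raw, p_corrected = NA_real_,
      correction_method = "bonferroni", n_hc = n_hc, n_patient = n_pat,
      stringsAsFactors = FALSE)
    manova_p <- c(manova_p, mv$p_raw)

    # shared permutations across the three components
    res <- residualize(as.matrix(d[, triple_cols]), covars(d))
    ord <- order(g)                   # group 1 rows first
    res <- res[ord, , drop = FALSE]
    ps <- make_perm_sets(n_hc + n_pat, n_hc, n_perm)
    t_obs <- apply(res, 2, function(v)
      abs(pooled_t(v, rep(c(1, 2), c(n_hc, n_pat)))))
    t_perm <- apply(res, 2, function(v) perm_abs_t(v, n_hc, n_pat, ps$idx))
    p_raw <- vapply(seq_along(t_obs), function(j) {
      if (ps$exhaustive) mean(t_perm[, j] >= t_obs[j] - 1e-12)
      else (1 + sum(t_perm[, j] >= t_obs[j] - 1e-12)) / (1 + nrow(t_perm))
    }, numeric(1))
    p_corr <- if (correction == "max_stat_fwe")
      correct_multiplicity(p_raw, "max_stat_fwe", perm_stats = t_perm,
                           stat_obs = t_obs, exhaustive = ps$exhaustive)
    else correct_multiplicity(p_raw, "bonferroni")
    for (j in seq_along(triple_cols)) {
      rows[[length(rows) + 1]] <- data.frame(
        region = r, arm = "pv_component",
        feature = sub(paste0("^", r, "_"), "", triple_cols[j]),
        statistic = t_obs[j], p_raw = p_raw[j], p_corrected = p_corr[j],
        correction_method = correction, n_hc = n_hc, n_patient = n_pat,
        stringsAsFactors = FALSE)
    }

    gm <- global_mean_test(d[[mean_col]], g, covars(d))
    rows[[length(rows) + 1]] <- data.frame(
      region = r, arm = "global_mean", feature = "mean_t1",
      statistic = gm$statistic, p_raw = gm$p_raw, p_corrected = NA_real_,
      correction_method = "bonferroni", n_hc = n_hc, n_patient = n_pat,
      stringsAsFactors = FALSE)
    global_p <- c(global_p, gm$p_raw)
  }
  out <- do.call(rbind, rows)
  out$p_corrected[out$arm == "pv_manova"] <-
    correct_multiplicity(manova_p, "bonferroni")
  out$p_corrected[out$arm == "global_mean"] <-
    correct_multiplicity(global_p, "bonferroni")
  out
}

#' Write a human-readable comparison report
#'
#' @param results Data.frame from [run_comparison].
#' @param path Output text file.
#' @return The path, invisibly.
#' @export
write_comparison_report <- function(results, path) {
  fmt_p <- function(p) ifelse(p < 1e-4, format(p, digits = 2, scientific = TRUE),
                              sprintf("%.4f", p))
  lines <- c("Group comparison report",
             "=======================", "")
  for (r in unique(results$region)) {
    sub <- results[results$region == r, ]
    lines <- c(lines, paste0("Region: ", r),
               sprintf("  MANOVA (mu_gm, mu_wm, C_GM/C_WM): Pillai = %.4f, p = %s (corrected %s)",
                       sub$statistic[sub$arm == "pv_manova"],
                       fmt_p(sub$p_raw[sub$arm == "pv_manova"]),
                       fmt_p(sub$p_corrected[sub$arm == "pv_manova"])))
    comp <- sub[sub$arm == "pv_component", ]
    for (j in seq_len(nrow(comp)))
      lines <- c(lines, sprintf("    component %-7s |t| = %.3f, p = %s (corrected %s, %s)",
                                comp$feature[j], comp$statistic[j],
                                fmt_p(comp$p_raw[j]), fmt_p(comp$p_corrected[j]),
                                comp$correction_method[j]))
    gl <- sub[sub$arm == "global_mean", ]
    lines <- c(lines, sprintf("  Global mean T1: t = %.3f, p = %s (corrected %s)",
                              gl$statistic, fmt_p(gl$p_raw),
                              fmt_p(gl$p_corrected)),
               sprintf("  n: %d HC vs %d patients", sub$n_hc[1], sub$n_patient[1]),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
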
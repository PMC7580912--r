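# Cohort statistics layer: Spearman trend across the ordered severity
# stages, age/Q-score-adjusted ANCOVA with Benjamini-Hochberg pairwise
# post-hoc contrasts, Cohen's d, a-priori sample size from noncentral-t
# power, and ROC screening statistics.

#' Spearman rank correlation against ordered disease stage
#'
#' Midrank ties; two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param values per-eye parameter values.
#' @param stages ordered integer stages (0-4).
#' @return list with `rho` and `p_value`.
#' @export
spearman_stage <- function(values, stages) {
  ok <- !is.na(values) & !is.na(stages)
  values <- values[ok]; stages <- stages[ok]
  n <- length(values)
  if (n < 3) stop("need at least 3 eyes")
  if (sd(values) == 0 || sd(stages) == 0)
    stop("undefined correlation: zero variance")
  rho <- stats::cor(rank(values), rank(stages))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Covariate-adjusted ANCOVA across severity stages
#'
#' Fits `value ~ factor(stage) + age + q_score` by least squares and reports
#' per-stage adjusted means (model predictions with both covariates at their
#' whole-sample means), the group-effect F-test p-value (stage term dropped
#' from the full model), covariate coefficients, and the material needed for
#' post-hoc contrasts.
#'
#' @param values per-eye parameter values.
#' @param stages integer stages (at least 2 distinct).
#' @param age,q_score covariates.
#' @return list of class `ancova_result` with `adjusted_means`, `overall_p`,
#'   `coefficients`, `residual_df`, plus internal `fit` context.
#' @export
ancova_adjusted_means <- function(values, stages, age, q_score) {
  ok <- stats::complete.cases(values, stages, age, q_score)
  dat <- data.frame(value = values[ok], stage = factor(stages[ok]),
                    age = age[ok], q_score = q_score[ok])
  if (nlevels(dat$stage) < 2) stop("need at least 2 stages")
  # constant covariates carry no information and would make the design
  # singular; drop them (a cohort with identical covariates needs no
  # adjustment, and the two-group no-covariate case reduces to the t-test)
  covars <- c("age", "q_score")[c(sd(dat$age) > 0, sd(dat$q_score) > 0)]
  fit <- lm(stats::reformulate(c("stage", covars), "value"), data = dat)
  if (any(is.na(coef(fit))))
    stop("singular ANCOVA design (collinear stage indicators/covariates)")
  full_rss <- sum(fit$residuals^2)
  red <- lm(stats::reformulate(if (length(covars)) covars else "1", "value"),
            data = dat)
  red_rss <- sum(red$residuals^2)
  df1 <- nlevels(dat$stage) - 1L
  df2 <- fit$df.residual
  fstat <- ((red_rss - full_rss) / df1) / (full_rss / df2)
  overall_p <- pf(fstat, df1, df2, lower.tail = FALSE)
  newd <- data.frame(stage = factor(levels(dat$stage),
                                    levels = levels(dat$stage)),
                     age = mean(dat$age), q_score = mean(dat$q_score))
  adj <- predict(fit, newdata = newd)
  names(adj) <- levels(dat$stage)
  cf_cov <- structure(rep(NA_real_, 2), names = c("age", "q_score"))
  cf_cov[covars] <- coef(fit)[covars]
  structure(list(adjusted_means = adj, overall_p = overall_p,
                 f_statistic = fstat,
                 coefficients = cf_cov,
                 residual_df = df2, fit = fit, data = dat),
            class = "ancova_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_p[i] = min over j with p_(j) >= p_(i) of (m / rank_j) * p_(j)`,
#' capped at 1; controls the false discovery rate across one family of
#' comparisons.
#'
#' @param p vector of raw p-values.
#' @return adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Pairwise post-hoc contrasts of adjusted means
#'
#' Tests every pair of stages using the ANCOVA model's pooled residual
#' variance: the contrast of adjusted means equals the difference of stage
#' coefficients (covariates cancel), its standard error comes from the model
#' covariance matrix, and the t-test uses the residual degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted across the pairs of this one
#' parameter.
#'
#' @param model an `ancova_result` (should follow a significant overall
#'   test; not enforced here).
#' @param fdr false-discovery-rate level for the `significant` flags.
#' @return data.frame with columns `stage_a`, `stage_b`, `diff`, `se`,
#'   `raw_p`, `adj_p`, `significant`.
#' @export
pairwise_posthoc <- function(model, fdr = 0.05) {
  stopifnot(inherits(model, "ancova_result"))
  lev <- levels(model$data$stage)
  cf <- coef(model$fit)
  V <- vcov(model$fit)
  cname <- function(s) if (s == lev[1]) NA_character_ else paste0("stage", s)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    contrast <- numeric(length(cf))
    names(contrast) <- names(cf)
    for (s in pr[1]) if (!is.na(cname(s))) contrast[cname(s)] <- 1
    for (s in pr[2]) if (!is.na(cname(s))) contrast[cname(s)] <-
        contrast[cname(s)] - 1
    est <- sum(contrast * cf)
    se <- sqrt(drop(t(contrast) %*% V %*% contrast))
    tval <- est / se
    p <- 2 * pt(-abs(tval), df = model$residual_df)
    c(diff = est, se = se, raw_p = p)
  })
  out <- data.frame(stage_a = pairs[1, ], stage_b = pairs[2, ],
                    t(res), stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$raw_p)
  out$significant <- out$adj_p < fdr
  out
}

#' Cohen's d standardized mean difference
#'
#' `(mean_a - mean_b) / s_pooled` with the df-weighted pooled standard
#' deviation.
#'
#' @param group_a,group_b numeric vectors with at least 2 observations each.
#' @return list with `d`.
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("both groups need >= 2 observations")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("undefined effect size: zero pooled SD")
  list(d = (mean(group_a) - mean(group_b)) / sqrt(sp2))
}

#' Power of a two-sided two-sample t-test
#'
#' Exact noncentral-t power at effect size `d`, `n` per group.
#' @param n per-group sample size (>= 2).
#' @param d standardized effect size.
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
t_test_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- qt(1 - alpha / 2, df)
  pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
}

#' A-priori minimum per-group sample size
#'
#' Smallest integer `n` such that a two-sided two-sample t-test at level
#' `alpha` with `n` per group reaches the target power at effect size `d`,
#' found by incrementing `n` against the exact noncentral-t power.
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer per-group sample size.
#' @export
min_sample_size <- function(d, alpha = 0.05, power = 0.8) {
  if (!is.numeric(d) || d <= 0) stop("effect size d must be > 0")
  n <- 2L
  while (t_test_power(n, d, alpha) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size search exceeded 1e6")
  }
  n
}

#' ROC analysis for a screening contrast
#'
#' AUC by the Mann-Whitney rank statistic with midrank ties, oriented so
#' that AUC >= 0.5 in the stated direction (by default lower parameter
#' values indicate the positive class, matching reduced perfusion in more
#' severe disease).  The operating point maximizes Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher sensitivity.
#'
#' @param values parameter values.
#' @param labels logical (or 0/1): `TRUE` = positive class (e.g. severe
#'   NPDR).
#' @param direction `"<"` if lower values indicate positives (default),
#'   `">"` otherwise.
#' @return list with `auc`, `sensitivity`, `specificity`,
#'   `operating_threshold` (classify positive when `values <=` threshold for
#'   direction `"<"`, `>=` for `">"`).
#' @export
roc_analysis <- function(values, labels, direction = c("<", ">")) {
  direction <- match.arg(direction)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.logical(labels[ok])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  score <- if (direction == "<") -values else values
  r <- rank(score)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cand <- sort(unique(values))
  best <- NULL
  for (cth in cand) {
    pos_call <- if (direction == "<") values <= cth else values >= cth
    sn <- sum(pos_call & labels) / n1
    sp <- sum(!pos_call & !labels) / n0
    j <- sn + sp - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sn > best$sn)) {
      best <- list(j = j, sn = sn, sp = sp, th = cth)
    }
  }
  list(auc = auc, sensitivity = best$sn, specificity = best$sp,
       operating_threshold = best$th)
}

#' Full cohort statistics report
#'
#' For each requested parameter: the Spearman stage trend, the
#' age/Q-score-adjusted ANCOVA (per-stage adjusted means and overall p), and
#' the BH-adjusted pairwise contrast matrix; plus ROC screening rows for the
#' configured parameters (default contrast: severe NPDR, stage 4, vs mild +
#' moderate NPDR, stages 2-3).  Parameters whose analysis fails (e.g. a
#' single-stage cohort) are reported in `errors` and the rest of the report
#' is still produced.
#'
#' @param records eye table (data.frame).
#' @param params character vector of parameter column names.
#' @param roc_params parameters for ROC screening (subset of `params`).
#' @param fdr FDR level for post-hoc significance flags.
#' @param roc_positive_stages,roc_negative_stages stages defining the ROC
#'   contrast.
#' @return list of class `cohort_report` with data.frames `spearman`,
#'   `ancova`, `pairwise`, `roc`, and a named character vector `errors`.
#' @export
run_cohort_report <- function(records, params,
                              roc_params = intersect(
                                c("SCP_VD", "SCP_VLD", "MCP_VD"), params),
                              fdr = 0.05,
                              roc_positive_stages = 4L,
                              roc_negative_stages = c(2L, 3L)) {
  validate_eye_table(records)
  miss <- setdiff(params, names(records))
  if (length(miss))
    stop("parameter(s) absent from the eye table: ",
         paste(miss, collapse = ", "))
  sp_rows <- list(); an_rows <- list(); pw_rows <- list(); roc_rows <- list()
  errors <- character(0)
  stage_names <- paste0("stage", 0:4)
  for (p in params) {
    v <- records[[p]]
    res <- tryCatch({
      sp <- spearman_stage(v, records$stage)
      an <- ancova_adjusted_means(v, records$stage, records$age,
                                  records$q_score)
      pw <- pairwise_posthoc(an, fdr = fdr)
      list(sp = sp, an = an, pw = pw)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[p] <- conditionMessage(res)
      next
    }
    sp_rows[[p]] <- data.frame(parameter = p, rho = res$sp$rho,
                               p_value = res$sp$p_value)
    adj <- rep(NA_real_, 5)
    names(adj) <- as.character(0:4)
    adj[names(res$an$adjusted_means)] <- res$an$adjusted_means
    an_rows[[p]] <- data.frame(parameter = p, t(adj),
                               overall_p = res$an$overall_p,
                               check.names = FALSE)
    pw_rows[[p]] <- cbind(parameter = p, res$pw)
  }
  for (p in roc_params) {
    v <- records[[p]]
    sel <- records$stage %in% c(roc_positive_stages, roc_negative_stages)
    res <- tryCatch(
      roc_analysis(v[sel], records$stage[sel] %in% roc_positive_stages),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[paste0(p, "_roc")] <- conditionMessage(res)
      next
    }
    roc_rows[[p]] <- data.frame(parameter = p, auc = res$auc,
                                sensitivity = res$sensitivity,
                                specificity = res$specificity,
                                operating_threshold = res$operating_threshold)
  }
  bindrows <- function(x) if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE)))
    else NULL
  structure(list(spearman = bindrows(sp_rows), ancova = bindrows(an_rows),
                 pairwise = bindrows(pw_rows), roc = bindrows(roc_rows),
                 errors = errors),
            class = "cohort_report")
}

#' Write a cohort report to CSV files
#'
#' Writes `spearman.csv`, `ancova_adjusted_means.csv`,
#' `pairwise_posthoc.csv` and `roc.csv` (those present) into `dir`.
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(spearman = "spearman.csv", ancova = "ancova_adjusted_means.csv",
             pairwise = "pairwise_posthoc.csv", roc = "roc.csv")
  for (nm in names(files)) {
    if (!is.null(report[[nm]]))
      write.csv(report[[nm]], file.path(dir, files[nm]), row.names = FALSE)
  }
  if (length(report$errors))
    writeLines(paste(names(report$errors), report$errors, sep = ": "),
               file.path(dir, "errors.txt"))
  invisible(dir)
}
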
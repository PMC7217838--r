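# Cohort-level statistics: Fisher exact with crude (cross-product) odds
# ratios, Mann-Whitney U, ROC/Youden dichotomization of the load,
# multivariable logistic regression with Wald intervals, and
# simulation-based power for the two-group Fisher design.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities of tables (at
#' the observed margins) no more likely than the observed one — the
#' conventional definition, as implemented by [stats::fisher.test()].
#' The reported odds ratio is the cross-product (ad/bc) "crude" OR by
#' default, which is what epidemiological reports quote; the
#' conditional-MLE OR of `fisher.test` is available via `or_method`.
#'
#' @param table 2x2 matrix `[[a, b], [c, d]]`, rows = groups, columns =
#'   outcome present/absent.
#' @param or_method `"cross_product"` or `"cmle"`.
#' @return list: `odds_ratio`, `p_value`, `degenerate` (`TRUE` when a
#'   margin is zero — then p = 1 — or when the cross-product is
#'   undefined/infinite).
#' @export
fisherExact2x2 <- function(table, or_method = c("cross_product", "cmle")) {
  or_method <- match.arg(or_method)
  table <- matrix(as.numeric(table), 2L, 2L)
  if (any(table < 0) || anyNA(table)) stop("table entries must be >= 0")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, degenerate = TRUE))
  ft <- fisher.test(table)
  or <- if (or_method == "cross_product") (a * d) / (b * c_)
        else unname(ft$estimate)
  list(odds_ratio = or, p_value = ft$p.value,
       degenerate = !is.finite(or) || or == 0)
}

#' Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()] (exact when both samples are small and
#' tie-free, tie-corrected normal approximation with continuity
#' correction otherwise) and reports the U statistic for `x` and its
#' AUC equivalent U/(n1 n2), in which tied pairs count one half.
#'
#' @param x,y numeric samples (non-empty).
#' @return list: `U`, `p_value` (two-sided), `auc_equivalent`.
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (all(x[1] == c(x, y))) {
    # fully tied data: U = n1 n2 / 2 and no evidence either way
    return(list(U = length(x) * length(y) / 2, p_value = 1,
                auc_equivalent = 0.5))
  }
  wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, p_value = wt$p.value,
       auc_equivalent = U / (length(x) * length(y)))
}

#' ROC analysis and Youden-optimal cutoff for the load
#'
#' Thresholds are the observed load values; a patient is called high
#' when load > threshold. The chosen cutoff maximizes Youden's
#' J = sensitivity + specificity - 1, with ties broken toward the lower
#' threshold (the more sensitive rule). AUC is computed by trapezoidal
#' integration of the ROC points, which equals the Mann-Whitney
#' U/(n1 n2) with tied pairs counted one half.
#'
#' @param loads numeric self-antigen loads.
#' @param groups vector with two classes; `positive` marks the positive
#'   class (default `"early"`).
#' @param positive positive-class label.
#' @return list of class `RocAnalysis`: `thresholds`, `sensitivity`,
#'   `specificity`, `youden`, `auc`, `chosen_cutoff`,
#'   `youden_at_cutoff`.
#' @export
rocAndCutoff <- function(loads, groups, positive = "early") {
  if (length(loads) != length(groups))
    stop("loads and groups must have equal length")
  pos <- groups == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present to compute an ROC curve")
  th <- sort(unique(loads))
  sens <- vapply(th, function(t) mean(loads[pos] > t), numeric(1))
  spec <- vapply(th, function(t) mean(loads[!pos] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # th is ascending, so [1] is the lowest
  # ROC points: (FPR, TPR) per threshold plus the (0,0) and (1,1) ends
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = th, sensitivity = sens, specificity = spec,
                 youden = j, auc = auc, chosen_cutoff = th[best],
                 youden_at_cutoff = j[best], positive = positive),
            class = "RocAnalysis")
}

#' @export
print.RocAnalysis <- function(x, ...) {
  cat("ROC analysis (positive class: ", x$positive, ")\n", sep = "")
  cat(sprintf("  AUC = %.3f\n", x$auc))
  cat(sprintf("  Youden-optimal cutoff: load > %g (J = %.3f)\n",
              x$chosen_cutoff, x$youden_at_cutoff))
  invisible(x)
}

#' Dichotomize loads at a cutoff
#'
#' High load means strictly greater than the cutoff.
#'
#' @param loads numeric loads.
#' @param cutoff numeric cutoff.
#' @return logical vector.
#' @export
dichotomizeLoad <- function(loads, cutoff) loads > cutoff

#' Multivariable logistic regression for onset group
#'
#' Fits early onset (= 1) against the study covariates — male gender,
#' education years, high self-antigen load, ApoE e4 carriage and mild
#' baseline CDR (0.5 or 1, entered as a binary indicator) — by maximum
#' likelihood, reporting odds ratios with Wald 95% intervals.
#' Non-convergence and (quasi-)complete separation are detected and
#' flagged, never silently returned as estimates.
#'
#' @param profiles `data.frame` with columns `onset_group`, `gender`,
#'   `education_years`, `apoe_e4`, `baseline_cdr`, `high_load`.
#' @param formula optional model formula over the derived columns
#'   `early`, `gender_male`, `education_years`, `high_load`, `apoe_e4`,
#'   `cdr_mild`.
#' @param conf_level Wald interval level.
#' @return list of class `LogisticFit`: `table` (term, estimate,
#'   odds_ratio, ci_lower, ci_upper, p_value), `converged`,
#'   `separation`, `model` (the `glm` object).
#' @export
fitLogistic <- function(profiles, formula = NULL, conf_level = 0.95) {
  d <- data.frame(
    early = as.integer(profiles$onset_group == "early"),
    gender_male = as.integer(profiles$gender == "male"),
    education_years = profiles$education_years,
    high_load = as.integer(profiles$high_load),
    apoe_e4 = as.integer(profiles$apoe_e4),
    cdr_mild = as.integer(profiles$baseline_cdr <= 1)
  )
  if (is.null(formula))
    formula <- early ~ gender_male + education_years + high_load +
      apoe_e4 + cdr_mild
  keep <- complete.cases(d[, all.vars(formula), drop = FALSE])
  if (!all(keep)) stop("missing covariate values for sample(s): ",
                       paste(profiles$sample_id[!keep], collapse = ", "))
  fit <- suppressWarnings(glm(formula, data = d, family = binomial()))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  pv <- 2 * stats::pnorm(-abs(cf / se))
  eps <- 1e-8
  separation <- !fit$converged ||
    any(abs(cf) > 15) ||
    all(fit$fitted.values > 1 - eps | fit$fitted.values < eps)
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    odds_ratio = exp(unname(cf)),
                    ci_lower = exp(unname(cf - z * se)),
                    ci_upper = exp(unname(cf + z * se)),
                    p_value = unname(pv), stringsAsFactors = FALSE)
  structure(list(table = tab, converged = fit$converged,
                 separation = separation, model = fit),
            class = "LogisticFit")
}

#' @export
print.LogisticFit <- function(x, digits = 3, ...) {
  cat("Binary logistic regression (outcome: early onset)\n")
  if (x$separation)
    cat("  WARNING: separation or non-convergence detected;",
        "estimates unreliable\n")
  t <- x$table[x$table$term != "(Intercept)", ]
  out <- data.frame(
    term = t$term,
    `OR (95% CI)` = sprintf("%.2f (%.2f-%.2f)", t$odds_ratio, t$ci_lower,
                            t$ci_upper),
    p = signif(t$p_value, digits), check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Simulation-based power for a two-group Fisher exact design
#'
#' For group sizes `n1`, `n2`, a baseline (group-2) outcome proportion
#' and an odds ratio, the group-1 proportion is implied by
#' p1 = OR * odds2 / (1 + OR * odds2). Replicate cohorts draw binomial
#' outcome counts in each group; power is the fraction of replicates in
#' which the two-sided Fisher exact test rejects at `alpha`
#' (p <= alpha). P-values are looked up from the precomputed grid over
#' all (count1, count2) outcomes, so replicates cost one table lookup.
#'
#' @param n1,n2 group sizes.
#' @param alpha two-sided type I error.
#' @param baseline_proportion outcome proportion in group 2.
#' @param odds_ratio effect size on the odds scale.
#' @param replicates Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list of class `PowerEstimate`: `power`, `mc_se` (Monte-Carlo
#'   standard error), `p1`, `p2`, `replicates`, plus the design fields.
#' @export
powerBySimulation <- function(n1, n2, alpha, baseline_proportion, odds_ratio,
                              replicates = 10000L, seed = 1L) {
  stopifnotScalarNumber(alpha, "alpha", 0, 1)
  stopifnotScalarNumber(baseline_proportion, "baseline_proportion", 0, 1)
  if (baseline_proportion %in% c(0, 1))
    stop("baseline_proportion must be strictly inside (0, 1)")
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  p2 <- baseline_proportion
  odds2 <- p2 / (1 - p2)
  p1 <- odds_ratio * odds2 / (1 + odds_ratio * odds2)
  pv <- matrix(NA_real_, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2)
    pv[i + 1L, j + 1L] <- fisher.test(
      matrix(c(i, n1 - i, j, n2 - j), 2L, byrow = TRUE))$p.value
  rej <- withLocalSeed(seed, {
    x1 <- rbinom(replicates, n1, p1)
    x2 <- rbinom(replicates, n2, p2)
    pv[cbind(x1 + 1L, x2 + 1L)] <= alpha
  })
  power <- mean(rej)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / replicates),
                 p1 = p1, p2 = p2, n1 = n1, n2 = n2, alpha = alpha,
                 odds_ratio = odds_ratio, replicates = replicates),
            class = "PowerEstimate")
}

#' @export
print.PowerEstimate <- function(x, ...) {
  cat(sprintf(
    "Simulated power = %.3f (MC SE %.4f)\n  n1 = %d, n2 = %d, alpha = %g, OR = %g, p2 = %.3f -> p1 = %.3f\n",
    x$power, x$mc_se, x$n1, x$n2, x$alpha, x$odds_ratio, x$p2, x$p1))
  invisible(x)
}

#' Group-comparison summary table
#'
#' One row per characteristic, early and late columns, with a
#' Mann-Whitney p-value for continuous rows (mean +/- SD shown) and a
#' two-sided Fisher p-value for categorical rows (n (%) shown).
#'
#' @param profiles `data.frame` with columns `onset_group`, `gender`,
#'   `education_years`, `apoe_e4`, `baseline_cdr`,
#'   `self_antigen_load`, `high_load`.
#' @return `data.frame` of class `Table1Summary` with columns
#'   `early`, `late`, `p_value`.
#' @export
table1Summary <- function(profiles) {
  need <- c("onset_group", "gender", "education_years", "apoe_e4",
            "baseline_cdr", "self_antigen_load", "high_load")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("profiles missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    bad <- which(is.na(profiles[[col]]))
    if (length(bad))
      stop("missing ", col, " for sample ",
           (profiles$sample_id %||% seq_len(nrow(profiles)))[bad[1]])
  }
  e <- profiles[profiles$onset_group == "early", ]
  l <- profiles[profiles$onset_group == "late", ]
  contRow <- function(x_e, x_l) {
    mw <- mannWhitney(x_e, x_l)
    c(early = sprintf("%.2f ± %.2f", mean(x_e), sd(x_e)),
      late = sprintf("%.2f ± %.2f", mean(x_l), sd(x_l)),
      p_value = mw$p_value)
  }
  catRow <- function(b_e, b_l) {
    ft <- fisherExact2x2(matrix(c(sum(b_e), sum(!b_e), sum(b_l), sum(!b_l)),
                                2L, byrow = TRUE))
    c(early = sprintf("%d (%.1f%%)", sum(b_e), 100 * mean(b_e)),
      late = sprintf("%d (%.1f%%)", sum(b_l), 100 * mean(b_l)),
      p_value = ft$p_value)
  }
  rows <- rbind(
    n = c(nrow(e), nrow(l), NA),
    `Gender (male)` = catRow(e$gender == "male", l$gender == "male"),
    `Education (years)` = contRow(e$education_years, l$education_years),
    `Self-antigen load` = contRow(e$self_antigen_load, l$self_antigen_load),
    `High self-antigen load` = catRow(e$high_load, l$high_load),
    `ApoE (e4+)` = catRow(e$apoe_e4, l$apoe_e4),
    `Baseline CDR (0.5 or 1)` = catRow(e$baseline_cdr <= 1,
                                       l$baseline_cdr <= 1)
  )
  out <- data.frame(early = rows[, 1], late = rows[, 2],
                    p_value = as.numeric(rows[, 3]),
                    stringsAsFactors = FALSE)
  class(out) <- c("Table1Summary", "data.frame")
  out
}

#' @export
print.Table1Summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$p_value <- ifelse(is.na(y$p_value), "", sprintf("%.3f", y$p_value))
  print(y)
  invisible(x)
}
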
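#' Fit a logistic case/control model
#'
#' Maximum-likelihood logistic regression (IRLS via `glm`) of a binary
#' outcome on the given design terms, with Wald SE and p per term,
#' in-sample predicted probabilities, and the in-sample ROC AUC of those
#' probabilities. Rank-deficient designs are a hard error naming the
#' collinear columns; (quasi-)perfect separation is flagged, with
#' coefficients reported under a warning.
#'
#' @param cohort data frame containing `response` and every term.
#' @param terms character vector of covariate column names (may be empty for
#'   an intercept-only model).
#' @param response name of the binary outcome column.
#' @param label model label carried into the report.
#' @return A `model_report` list: `label`, `terms` (data frame with
#'   `term`, `estimate`, `se`, `z`, `p`), `auc`, `n`, `n_case`, `fitted`,
#'   `loglik`, `converged`, `separation`.
#' @export
fit_logistic <- function(cohort, terms = character(), response = "case",
                         label = paste(terms, collapse = "+")) {
  y <- cohort[[response]]
  if (is.null(y)) stop2("no column `", response, "` in cohort")
  if (length(unique(y[!is.na(y)])) < 2) stop2("outcome needs both classes")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- as.formula(paste(response, "~", rhs))
  mm <- stats::model.matrix(f, data = cohort)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop2("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = cohort, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_flag) warning("possible separation: fitted probabilities at 0/1")
  cf <- summary(fit)$coefficients
  prob <- predict(fit, type = "response")
  yy <- fit$model[[response]]
  auc <- if (length(unique(yy)) == 2) roc_auc(prob, yy)$auc else NA_real_
  structure(list(
    label = label,
    terms = data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                       z = cf[, 3], p = cf[, 4], row.names = NULL,
                       stringsAsFactors = FALSE),
    auc = auc, n = length(yy), n_case = sum(yy == 1),
    fitted = as.numeric(prob), loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged, separation = sep_flag
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s  n=%d (%d cases)  AUC=%.3f\n",
              x$label, x$n, x$n_case, x$auc))
  print(x$terms, digits = 3)
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney statistic (ties count one half), computed from
#' midranks; the curve enumerates every distinct threshold.
#'
#' @param scores numeric predictor (higher = more case-like).
#' @param labels binary labels (0/1 or logical).
#' @return List: `auc` and `curve` (data frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) stop2("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

# Placement values: V10[i] = mean_j psi(x_i, y_j) over controls, V01[j]
# likewise over cases; psi = 1, 1/2, 0 for case score >, =, < control score.
.placements <- function(pred, labels) {
  x <- pred[labels == 1]; y <- pred[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two predictors evaluated on the same samples and
#' labels, using the placement-value covariance estimate of
#' `var(AUC_a - AUC_b)`; two-sided p by default. Degenerate variance
#' (e.g. identical predictors) returns p = 1 by convention.
#'
#' @param pred_a,pred_b numeric predictors on the same samples.
#' @param labels binary labels shared by both predictors.
#' @param two_sided two-sided p-value (default); otherwise the one-sided
#'   alternative AUC_a > AUC_b.
#' @return List: `auc_a`, `auc_b`, `delta`, `var_delta`, `z`, `p`.
#' @export
delong_test <- function(pred_a, pred_b, labels, two_sided = TRUE) {
  labels <- as.integer(labels)
  if (length(pred_a) != length(labels) || length(pred_b) != length(labels))
    stop2("predictors and labels must have equal length")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop2("both classes must be present")
  pa <- .placements(pred_a, labels)
  pb <- .placements(pred_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (!is.finite(var_delta) || var_delta <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- if (two_sided) 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
       var_delta = var_delta, z = z, p = p)
}

#' One-sided comparison of case and control score means
#'
#' Welch two-sample t-test with alternative "case mean exceeds control
#' mean".
#'
#' @param scores numeric scores (or a [score_set()]).
#' @param labels binary case labels.
#' @return List: `mean_case`, `mean_control`, `t`, `df`, `p`.
#' @export
compare_score_means <- function(scores, labels) {
  if (inherits(scores, "score_set")) scores <- scores$scores
  labels <- as.integer(labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  if (length(x) < 2 || length(y) < 2) stop2("both groups need >= 2 samples")
  tt <- t.test(x, y, alternative = "greater", var.equal = FALSE)
  list(mean_case = mean(x), mean_control = mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Genotype principal components for population structure
#'
#' Standardizes each variant's dosage by `2p` and `sqrt(2p(1-p))` (allele
#' frequency `p` from the data, missing entries mean-imputed), then takes
#' the top `k` left singular vectors. Sign convention: each component is
#' flipped so its largest-magnitude variant loading is positive, making
#' repeated runs bit-identical.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (default 3).
#' @return List: `scores` (n x k matrix, columns `PC1..PCk`),
#'   `variance_share` (length k).
#' @export
pca_genotypes <- function(gm, k = 3) {
  d <- gm$dosages
  af <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(af) & af > 0 & af < 1
  d <- d[, keep, drop = FALSE]; af <- af[keep]
  if (k > min(dim(d)) - 1) stop2("k exceeds the matrix rank budget")
  M <- sweep(d, 2, 2 * af)
  M[is.na(M)] <- 0
  M <- sweep(M, 2, sqrt(2 * af * (1 - af)), "/")
  sv <- svd(M, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k), 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- gm$sample_ids
  list(scores = scores, variance_share = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Run the standalone-PRS threshold sweep
#'
#' For each p-value threshold: select variants (`p <=` threshold), compute
#' the standardized standard-formula score, and fit the standalone logistic
#' model `case ~ PRS`. Thresholds with no surviving variants, constant
#' scores, or non-converged fits are recorded with NA estimates.
#'
#' @param variants clumped, harmonized variant data frame.
#' @param gm a [genotype_matrix()].
#' @param cohort cohort data frame with a `case` column.
#' @param thresholds numeric vector (default [prs_thresholds()]).
#' @return Data frame: `threshold`, `n_snps`, `estimate` (standardized PRS
#'   coefficient), `se`, `p`, `auc`, `converged`.
#' @export
sweep_thresholds <- function(variants, gm, cohort, thresholds = prs_thresholds()) {
  rows <- lapply(thresholds, function(th) {
    sel <- apply_threshold(variants, th)
    base <- data.frame(threshold = th, n_snps = nrow(sel), estimate = NA_real_,
                       se = NA_real_, p = NA_real_, auc = NA_real_,
                       converged = FALSE)
    if (!nrow(sel)) return(base)
    ss <- score_standard(sel, gm, p_threshold = th)
    if (sd(ss$scores) == 0) return(base)
    dat <- cohort
    dat$PRS <- standardize_scores(ss)$scores[dat$sample_id]
    rep <- fit_logistic(dat, "PRS", label = sprintf("standalone p<=%g", th))
    i <- match("PRS", rep$terms$term)
    base$estimate <- rep$terms$estimate[i]
    base$se <- rep$terms$se[i]
    base$p <- rep$terms$p[i]
    base$auc <- rep$auc
    base$converged <- rep$converged
    base
  })
  do.call(rbind, rows)
}

#' Select the optimal p-value threshold from a sweep
#'
#' Chooses the threshold whose standardized PRS coefficient (effect size)
#' is largest — most positive — among converged fits; ties go to the
#' smaller threshold.
#'
#' @param sweep data frame from [sweep_thresholds()].
#' @return List: `threshold` and the full `sweep` table.
#' @export
select_threshold <- function(sweep) {
  ok <- which(sweep$converged & !is.na(sweep$estimate))
  if (!length(ok)) stop2("no converged sweep entries")
  best <- max(sweep$estimate[ok])
  cand <- ok[sweep$estimate[ok] == best]
  chosen <- cand[which.min(sweep$threshold[cand])]
  list(threshold = sweep$threshold[chosen], sweep = sweep)
}

#' Restrict a cohort to APOE e3 homozygotes
#'
#' Retains genotype "33" only. Downstream model designs for this stratum
#' should drop the `e4_count` term (constant zero here).
#'
#' @param cohort data frame with an `apoe_genotype` column.
#' @return The e3/e3 sub-cohort.
#' @export
stratify_e3_homozygotes <- function(cohort) {
  if (is.null(cohort$apoe_genotype)) stop2("no `apoe_genotype` column")
  cohort[cohort$apoe_genotype == "33", , drop = FALSE]
}
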
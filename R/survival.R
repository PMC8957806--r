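#' Validate left-truncated survival records
#'
#' Checks the delayed-entry contract: `entry_age < exit_age` for every row
#' (equality rejected), binary `event`, no missing times.
#'
#' @param records data frame with `entry_age`, `exit_age`, `event`.
#' @return `records`, invisibly, or a hard error.
#' @export
validate_survival_records <- function(records) {
  need <- c("entry_age", "exit_age", "event")
  if (!all(need %in% names(records)))
    stop2("records must have columns: ", paste(need, collapse = ", "))
  if (anyNA(records$entry_age) || anyNA(records$exit_age) || anyNA(records$event))
    stop2("survival columns must not contain NA")
  if (any(records$entry_age >= records$exit_age))
    stop2("entry_age must be strictly less than exit_age for every subject")
  if (!all(records$event %in% c(0, 1))) stop2("event must be 0/1")
  invisible(records)
}

#' Left-truncated right-censored proportional-hazards fit
#'
#' Cox partial-likelihood fit on the age axis with delayed entry: the risk
#' set at an event age `t` contains subjects with `entry_age < t <=
#' exit_age`. Breslow tie handling by default (Efron behind the flag).
#' Reports per-term risk ratios `exp(coef)` with 95% Wald confidence
#' intervals and the model likelihood-ratio p versus the null.
#'
#' @param records data frame with `entry_age`, `exit_age`, `event` and all
#'   design columns.
#' @param terms character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `ph_report` list: `terms` (data frame with `term`, `coef`,
#'   `se`, `p`, `risk_ratio`, `rr_lower`, `rr_upper`), `n`, `n_events`,
#'   `lr_stat`, `lr_df`, `lr_p`, and the underlying `fit`.
#' @export
fit_ph_left_truncated <- function(records, terms, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  validate_survival_records(records)
  if (sum(records$event) < 1) stop2("at least one event is required")
  if (!length(terms)) stop2("supply at least one design term")
  if (min(records$entry_age) >= max(records$exit_age[records$event == 1]))
    stop2("no risk-set overlap: every entry follows every event")
  f <- as.formula(paste("survival::Surv(entry_age, exit_age, event) ~",
                        paste(terms, collapse = " + ")))
  fit <- survival::coxph(f, data = records, ties = ties)
  cf <- summary(fit)$coefficients
  z <- qnorm(0.975)
  lr_stat <- 2 * (fit$loglik[2] - fit$loglik[1])
  lr_df <- length(coef(fit))
  structure(list(
    terms = data.frame(
      term = rownames(cf), coef = cf[, "coef"], se = cf[, "se(coef)"],
      p = cf[, "Pr(>|z|)"], risk_ratio = exp(cf[, "coef"]),
      rr_lower = exp(cf[, "coef"] - z * cf[, "se(coef)"]),
      rr_upper = exp(cf[, "coef"] + z * cf[, "se(coef)"]),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    n = nrow(records), n_events = sum(records$event),
    lr_stat = lr_stat, lr_df = lr_df,
    lr_p = pchisq(lr_stat, lr_df, lower.tail = FALSE),
    fit = fit
  ), class = "ph_report")
}

#' @export
print.ph_report <- function(x, ...) {
  cat(sprintf("<ph_report> n=%d, events=%d, LR p=%.3g\n", x$n, x$n_events, x$lr_p))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Kaplan-Meier curves with delayed entry
#'
#' Product-limit survival estimates whose at-risk counts respect
#' `entry_age` (left truncation). Curves are reported only from the first
#' age at which the group's at-risk count reaches `min_at_risk`.
#'
#' @param records data frame with `entry_age`, `exit_age`, `event`.
#' @param groups optional group label per row; `NULL` for one curve.
#' @param min_at_risk minimum at-risk count before the curve is reported.
#' @return Data frame: `group`, `age`, `at_risk`, `events`, `survival`.
#' @export
km_curve <- function(records, groups = NULL, min_at_risk = 1) {
  validate_survival_records(records)
  if (is.null(groups)) groups <- rep("all", nrow(records))
  if (length(groups) != nrow(records)) stop2("groups must align with records")
  out <- lapply(split(seq_len(nrow(records)), groups), function(idx) {
    if (!length(idx)) return(NULL)
    r <- records[idx, , drop = FALSE]
    sf <- survival::survfit(
      survival::Surv(entry_age, exit_age, event) ~ 1, data = r)
    keep <- cumsum(sf$n.risk >= min_at_risk) > 0
    data.frame(group = as.character(groups[idx[1]]), age = unname(sf$time[keep]),
               at_risk = sf$n.risk[keep], events = sf$n.event[keep],
               survival = sf$surv[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' K-group log-rank test with delayed entry
#'
#' Log-rank (Mantel-Haenszel) test whose risk sets honor left truncation:
#' at each distinct event age `t`, group `g` contributes its subjects with
#' `entry_age < t <= exit_age`. Uses the hypergeometric variance with the
#' standard multi-group covariance matrix; chi-square on `k - 1` degrees of
#' freedom via a generalized inverse. With zero events overall the statistic
#' is undefined and reported as such (`defined = FALSE`, `p = NA`).
#'
#' @param records data frame with `entry_age`, `exit_age`, `event`.
#' @param groups group label per row (>= 2 distinct values).
#' @return List: `chisq`, `df`, `p`, `observed`, `expected`, `defined`.
#' @export
logrank_test <- function(records, groups) {
  validate_survival_records(records)
  groups <- as.character(groups)
  if (length(groups) != nrow(records)) stop2("groups must align with records")
  lev <- sort(unique(groups))
  k <- length(lev)
  if (k < 2) stop2("log-rank needs at least 2 groups")
  if (sum(records$event) == 0)
    return(list(chisq = NA_real_, df = k - 1L, p = NA_real_,
                observed = setNames(numeric(k), lev),
                expected = setNames(numeric(k), lev), defined = FALSE))
  g <- match(groups, lev)
  times <- sort(unique(records$exit_age[records$event == 1]))
  O <- numeric(k); E <- numeric(k); V <- matrix(0, k, k)
  for (t in times) {
    at_risk <- records$entry_age < t & records$exit_age >= t
    n_t <- sum(at_risk)
    if (n_t == 0) next
    d_g <- vapply(seq_len(k), function(j)
      sum(records$event == 1 & records$exit_age == t & g == j), numeric(1))
    n_g <- vapply(seq_len(k), function(j) sum(at_risk & g == j), numeric(1))
    d_t <- sum(d_g)
    if (d_t == 0) next
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      frac <- n_g / n_t
      V <- V + d_t * (n_t - d_t) / (n_t - 1) * (diag(frac, k) - tcrossprod(frac))
    }
  }
  idx <- seq_len(k - 1)
  u <- (O - E)[idx]
  Vi <- tryCatch(solve(V[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(Vi)) {
    sv <- svd(V[idx, idx, drop = FALSE])
    pos <- sv$d > max(sv$d) * 1e-10
    Vi <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  }
  chisq <- max(as.numeric(t(u) %*% Vi %*% u), 0)
  list(chisq = chisq, df = k - 1L,
       p = pchisq(chisq, k - 1, lower.tail = FALSE),
       observed = setNames(O, lev), expected = setNames(E, lev),
       defined = TRUE)
}

#' Split samples into score tertiles
#'
#' Cuts at the empirical 1/3 and 2/3 quantiles (R's default type-7
#' definition). Values exactly at a cut go to the lower group; heavy ties at
#' a cut therefore inflate the lower group, which is reported.
#'
#' @param scores numeric vector or [score_set()].
#' @return Factor with levels `low`, `mid`, `high` (attribute `sizes`
#'   records group sizes).
#' @export
tertile_groups <- function(scores) {
  if (inherits(scores, "score_set")) scores <- scores$scores
  if (length(scores) < 3) stop2("tertiles need at least 3 samples")
  if (sd(scores) == 0) stop2("cannot split constant scores")
  q <- quantile(scores, c(1, 2) / 3, type = 7, names = FALSE)
  lab <- ifelse(scores <= q[1], "low", ifelse(scores <= q[2], "mid", "high"))
  out <- factor(lab, levels = c("low", "mid", "high"))
  attr(out, "sizes") <- table(out)
  out
}
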
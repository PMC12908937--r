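#' Tabulate 3-AFC performance per subject and pair
#'
#' Aggregates trial-level records into one row per (subject, pair):
#' number of trials, accuracy, mean and median response time, joined with
#' the per-pair predictor values (differential instability percentages,
#' friction-coefficient differences, and so on). Every pair appearing in
#' the trials must have predictor values.
#'
#' @param table A `behavioral_table`.
#' @param predictors Data frame with a `pair_label` column plus one
#'   numeric column per predictor.
#' @return Data frame of class `pair_summary`.
#' @export
tabulate_behavior <- function(table, predictors) {
  table <- behavioral_table(as.data.frame(table))
  if (!"pair_label" %in% names(predictors))
    abort("predictors must contain a pair_label column",
          "frinstab_validation_error")
  missing_pairs <- setdiff(unique(table$pair_label), predictors$pair_label)
  if (length(missing_pairs))
    abort(paste("no predictor values for pair(s):",
                paste(missing_pairs, collapse = ", ")),
          "frinstab_join_error")
  agg <- do.call(rbind, lapply(
    split(as.data.frame(table),
          list(table$subject_id, table$pair_label), drop = TRUE),
    function(d) data.frame(subject_id = d$subject_id[1],
                           pair_label = d$pair_label[1],
                           n_trials = nrow(d),
                           accuracy = mean(d$correct),
                           mean_rt = mean(d$response_time),
                           median_rt = stats::median(d$response_time),
                           stringsAsFactors = FALSE)))
  out <- merge(agg, predictors, by = "pair_label", sort = TRUE)
  out <- out[order(out$pair_label, out$subject_id), ]
  rownames(out) <- NULL
  class(out) <- c("pair_summary", class(out))
  out
}

#' One-sample t-test of accuracies against chance
#'
#' In a 3-AFC task chance accuracy is 1/3; this tests per-subject
#' accuracies against it (two-sided). With zero variance the test
#' degenerates: p = 0 if the common value differs from chance, 1 if it
#' equals it.
#'
#' @param accuracies Per-subject accuracy values (n >= 2).
#' @param chance Chance level, default 1/3.
#' @return List with `t`, `p`, `mean` and `df`.
#' @export
chance_test <- function(accuracies, chance = 1 / 3) {
  if (length(accuracies) < 2L)
    abort("need at least two subjects", "frinstab_validation_error")
  m <- mean(accuracies)
  if (stats::sd(accuracies) == 0) {
    return(list(t = if (m == chance) 0 else sign(m - chance) * Inf,
                p = if (m == chance) 1 else 0, mean = m,
                df = length(accuracies) - 1L))
  }
  tt <- stats::t.test(accuracies, mu = chance)
  list(t = unname(tt$statistic), p = tt$p.value, mean = m,
       df = unname(tt$parameter))
}

#' Two-sided Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Compares two sets of subject-level accuracies. Ties receive mid-ranks.
#' For combined sample sizes up to 20 the null distribution of the
#' rank-sum statistic is obtained by exact enumeration over all
#' assignments of the pooled ranks (valid under ties as well); larger
#' samples use the normal approximation with tie correction and
#' continuity correction. The two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`; with every value tied across
#' both groups p = 1.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @return List with `statistic` (rank sum of `a`), `p`, and `method`.
#' @export
rank_sum_test <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n < 3L || m < 3L)
    abort("need at least 3 observations per group",
          "frinstab_validation_error")
  pooled <- c(a, b)
  r <- rank(pooled)           # mid-ranks for ties
  w <- sum(r[seq_len(n)])
  if (stats::sd(pooled) == 0)
    return(list(statistic = w, p = 1, method = "degenerate (all tied)"))
  if (n + m <= 20L) {
    sets <- utils::combn(n + m, n)
    ws <- colSums(matrix(r[sets], nrow = n))
    p <- min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + m + 1) / 2
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
    sigma2 <- n * m / 12 * ((n + m + 1) - tie_corr)
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p = p, method = method)
}

# Join trial-level records with one predictor value per pair.
join_predictor <- function(table, predictors, predictor) {
  stopifnot(all(predictor %in% setdiff(names(predictors), "pair_label")))
  idx <- match(table$pair_label, predictors$pair_label)
  if (anyNA(idx))
    abort("trial pairs missing from predictor table", "frinstab_join_error")
  d <- data.frame(correct = as.numeric(table$correct),
                  response_time = table$response_time,
                  subject_id = table$subject_id,
                  pair_label = table$pair_label,
                  stringsAsFactors = FALSE)
  for (p in predictor) d[[p]] <- predictors[[p]][idx]
  d
}

mm_fit <- function(model, family, d, predictor, outcome_by_pair) {
  beta <- lme4::fixef(model)
  vc <- as.data.frame(lme4::VarCorr(model))
  subject_sd <- vc$sdcor[vc$grp == "subject_id"][1]
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- beta[predictor[1]] / se[predictor[1]]
  p <- 2 * stats::pnorm(-abs(z))
  r <- if (length(predictor) == 1L) {
    pr <- tapply(d[[predictor]], d$pair_label, mean)
    ob <- outcome_by_pair
    if (length(unique(pr)) > 1 && stats::sd(ob) > 0)
      stats::cor(ob, pr[names(ob)]) else NA_real_
  } else NA_real_
  structure(list(fixed = list(intercept = unname(beta["(Intercept)"]),
                              slope = unname(beta[predictor[1]]),
                              slope_se = unname(se[predictor[1]]),
                              slope_p = unname(p),
                              coefficients = beta),
                 random = list(subject_sd = subject_sd),
                 family = family,
                 descriptive_r = unname(r),
                 n_obs = nrow(d),
                 separation = unname(se[predictor[1]]) > 50,
                 model = model),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> %s, n = %d\n", x$family, x$n_obs))
  cat(sprintf("  slope %.4g (se %.3g, p = %.3g), subject sd %.3g, r = %.2f\n",
              x$fixed$slope, x$fixed$slope_se, x$fixed$slope_p,
              x$random$subject_sd, x$descriptive_r))
  invisible(x)
}

#' Mixed logistic model of discrimination accuracy
#'
#' Fits trial-level correctness as Bernoulli with a logit link, a fixed
#' slope on the chosen per-pair predictor (e.g. the differential
#' steady-sliding percentage) and a random intercept per subject, by
#' maximum likelihood (Laplace approximation, `lme4::glmer`). Alongside
#' the model slope and its Wald p-value, the fit reports a descriptive
#' Pearson r between the pair-level mean accuracies and the predictor,
#' the analogue of the correlation usually quoted with such plots.
#'
#' Multiple predictor names yield a multi-term model; slope inference and
#' the descriptive r then refer to the first term.
#'
#' @param table A `behavioral_table` (>= 2 subjects).
#' @param predictors Data frame of per-pair predictors (see
#'   [tabulate_behavior()]).
#' @param predictor Character: predictor column name(s).
#' @return A `mixed_model_fit`.
#' @export
fit_accuracy_glmm <- function(table, predictors, predictor) {
  table <- behavioral_table(as.data.frame(table))
  if (length(unique(table$subject_id)) < 2L)
    abort("need at least two subjects", "frinstab_validation_error")
  d <- join_predictor(table, predictors, predictor)
  if (length(unique(d[[predictor[1]]])) < 2L)
    abort("predictor must take at least two distinct values",
          "frinstab_validation_error")
  form <- stats::as.formula(paste("correct ~",
                                  paste(predictor, collapse = " + "),
                                  "+ (1 | subject_id)"))
  model <- tryCatch(
    lme4::glmer(form, data = d, family = stats::binomial()),
    error = function(e)
      abort(paste("accuracy GLMM did not converge:", conditionMessage(e)),
            "frinstab_convergence_error"))
  acc_by_pair <- tapply(d$correct, d$pair_label, mean)
  mm_fit(model, "binomial-logit", d, predictor, acc_by_pair)
}

#' Mixed model of log response time
#'
#' Response times are strictly positive and right-skewed, so they are
#' modelled on the log scale: Gaussian linear mixed model of `log(RT)`
#' with a fixed predictor slope (e.g. the differential stiction-spike
#' percentage) and a subject random intercept (`lme4::lmer`, ML fit).
#' Slope inference uses the Wald normal approximation; the descriptive r
#' correlates pair-level mean log response times with the predictor.
#'
#' @inheritParams fit_accuracy_glmm
#' @return A `mixed_model_fit`.
#' @export
fit_rt_model <- function(table, predictors, predictor) {
  table <- behavioral_table(as.data.frame(table))
  if (any(table$response_time <= 0))
    abort("response times must be positive", "frinstab_validation_error")
  d <- join_predictor(table, predictors, predictor)
  d$log_rt <- log(d$response_time)
  form <- stats::as.formula(paste("log_rt ~",
                                  paste(predictor, collapse = " + "),
                                  "+ (1 | subject_id)"))
  model <- tryCatch(
    suppressMessages(lme4::lmer(form, data = d, REML = FALSE)),
    error = function(e)
      abort(paste("RT model did not converge:", conditionMessage(e)),
            "frinstab_convergence_error"))
  rt_by_pair <- tapply(d$log_rt, d$pair_label, mean)
  mm_fit(model, "gaussian-identity-on-logRT", d, predictor, rt_by_pair)
}
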
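#' Fit a linear fixed- or mixed-effect model
#'
#' Dispatches on the formula: with a random-effect bar (e.g.
#' `(1 | participant)`) the model is fitted with `lme4::lmer`, otherwise
#' with `lm`. Maximum likelihood (not REML) is the default so that AIC
#' and likelihood-ratio comparisons between fits are valid; set
#' `ml = FALSE` for REML coefficient reporting.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param ml Fit by maximum likelihood (`TRUE`, default) or REML.
#' @return Object of class `model_fit`: list with the underlying
#'   `model`, a `coefficients` table (estimate, SE), `ranef_var` (named
#'   random-intercept variances, empty for fixed models), `sigma2`
#'   (residual variance), `logLik`, `AIC`, `edf` (free-parameter count,
#'   satisfying `AIC = -2 logLik + 2 edf` exactly), `ml`, and
#'   `singular` (TRUE when a variance component collapsed to zero; the
#'   fit is retained).
#' @export
fit_lmm <- function(formula, data, ml = TRUE) {
  mixed <- length(lme4::findbars(formula)) > 0
  if (mixed) {
    model <- lme4::lmer(formula, data = data, REML = !ml)
    vc <- as.data.frame(lme4::VarCorr(model))
    rv <- setNames(vc$vcov[vc$grp != "Residual"], vc$grp[vc$grp != "Residual"])
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(model)
    co <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
  } else {
    model <- lm(formula, data = data)
    rv <- numeric(0)
    sigma2 <- summary(model)$sigma^2
    singular <- FALSE
    co <- coef(model)
    se <- sqrt(diag(stats::vcov(model)))
  }
  ll <- logLik(model)
  structure(
    list(model = model, formula = formula,
         coefficients = data.frame(term = names(co), estimate = unname(co),
                                   se = unname(se), stringsAsFactors = FALSE),
         ranef_var = rv, sigma2 = sigma2,
         logLik = as.numeric(ll), edf = attr(ll, "df"),
         AIC = -2 * as.numeric(ll) + 2 * attr(ll, "df"),
         ml = ml, mixed = mixed, singular = singular),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s | logLik %.2f, edf %d, AIC %.2f%s\n",
              deparse(x$formula), x$logLik, x$edf, x$AIC,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

balanced_emmeans <- function(fit, factor, data) {
  # marginal means on a balanced grid of the categorical predictors,
  # numeric predictors held at their means; fixed effects only
  model <- fit$model
  tl <- attr(terms(if (fit$mixed) lme4::nobars(fit$formula) else fit$formula),
             "term.labels")
  tl <- tl[!grepl(":", tl)]
  grid <- list()
  for (v in tl) {
    col <- data[[v]]
    grid[[v]] <- if (is.numeric(col)) mean(col) else sort(unique(as.character(col)))
  }
  nd <- expand.grid(grid, stringsAsFactors = FALSE)
  pred <- if (fit$mixed) predict(model, newdata = nd, re.form = NA)
          else predict(model, newdata = nd)
  tapply(pred, nd[[factor]], mean)
}

#' Tukey post-hoc comparisons of a factor in a fitted model
#'
#' All pairwise contrasts of the factor's levels with single-step
#' (studentized multivariate normal) family-wise adjustment via
#' `multcomp::glht`. The table also reports, per the usual triangular
#' presentation, which level has the largest and smallest marginal mean
#' (computed on a balanced grid of the other fixed factors).
#'
#' @param fit A `model_fit` whose formula contains `factor` as a fixed
#'   main effect.
#' @param factor Name of the categorical predictor.
#' @param data The data used to fit (for the marginal-mean grid).
#' @param alpha Significance level used for the `significant` flag.
#' @return Object of class `tukey_table`: list with `comparisons` (data
#'   frame: level_a, level_b, estimate = mean(a) - mean(b), adjusted p,
#'   direction), `argmax`, `argmin`, `factor`, `alpha`.
#' @export
tukey_posthoc <- function(fit, factor, data, alpha = 0.05) {
  lv <- sort(unique(as.character(data[[factor]])))
  if (length(lv) < 2) stop("factor must have at least 2 levels")
  args <- setNames(list("Tukey"), factor)
  gl <- multcomp::glht(fit$model, linfct = do.call(multcomp::mcp, args))
  sm <- summary(gl, test = multcomp::adjusted("single-step"))
  nm <- rownames(sm$linfct)
  parts <- strsplit(nm, " - ", fixed = TRUE)
  est <- as.numeric(sm$test$coefficients)
  padj <- as.numeric(sm$test$pvalues)
  comp <- data.frame(
    level_a = vapply(parts, `[`, character(1), 1),
    level_b = vapply(parts, `[`, character(1), 2),
    estimate = est, p_adj = padj,
    direction = ifelse(est > 0, "a>b", ifelse(est < 0, "a<b", "a=b")),
    significant = padj < alpha,
    stringsAsFactors = FALSE
  )
  em <- balanced_emmeans(fit, factor, data)
  structure(
    list(comparisons = comp, marginal_means = em,
         argmax = names(em)[which.max(em)], argmin = names(em)[which.min(em)],
         factor = factor, alpha = alpha),
    class = "tukey_table"
  )
}

#' @export
print.tukey_table <- function(x, ...) {
  cat(sprintf("<tukey_table> factor %s: max %s, min %s\n",
              x$factor, x$argmax, x$argmin))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Within-background and within-task mixed models of PC scores
#'
#' Fits, for each component and each level of the conditioning factor,
#' the mixed model `PC ~ other_factor + subregion + (1 | participant)`
#' on channel-level scores, with a Tukey table for the factor of
#' interest: conditioning on `background` compares tasks
#' (within-background modelling); conditioning on `task` compares
#' backgrounds (within-task modelling).
#'
#' @param scores Channel-level score table from [channel_scores()] with
#'   a `subregion` column.
#' @param within Conditioning factor: `"background"` or `"task"`.
#' @param k Number of components to model.
#' @param alpha Significance level for the Tukey flags.
#' @return Nested list `result[[level]][[PC]]`, each element a list with
#'   `fit` (a `model_fit`) and `tukey` (a `tukey_table`).
#' @export
within_condition_models <- function(scores, within = c("background", "task"),
                                    k = 9, alpha = 0.05) {
  within <- match.arg(within)
  other <- if (within == "background") "task" else "background"
  out <- list()
  for (lev in sort(unique(scores[[within]]))) {
    sub <- scores[scores[[within]] == lev, ]
    if (length(unique(sub[[other]])) < 2) next
    out[[lev]] <- list()
    for (pc in paste0("PC", seq_len(k))) {
      f <- as.formula(paste0(pc, " ~ ", other, " + subregion + (1 | participant)"))
      fit <- fit_lmm(f, sub)
      out[[lev]][[pc]] <- list(fit = fit,
                               tukey = tukey_posthoc(fit, other, sub, alpha))
    }
  }
  out
}

#' Exam z-scores referenced to the silence condition
#'
#' Standardizes the keywords-correct counts per topic using the mean and
#' SD of that topic's scores in the pink-noise (lecture in silence)
#' condition across all participants.
#'
#' @param exam Data frame with columns `participant`, `topic`,
#'   `background`, `keywords_correct`.
#' @param pink Level of `background` that denotes silence.
#' @return The input with a `z` column appended; per-topic `mu_pink` and
#'   `sigma_pink` in attribute `"pink_stats"`. Topics whose pink SD is
#'   zero are flagged there and get `NA` z-scores.
#' @export
exam_zscores <- function(exam, pink = "PK") {
  need <- c("participant", "topic", "background", "keywords_correct")
  stopifnot(all(need %in% names(exam)))
  topics <- sort(unique(exam$topic))
  stats_df <- do.call(rbind, lapply(topics, function(tp) {
    pkrows <- exam$keywords_correct[exam$topic == tp & exam$background == pink]
    if (length(pkrows) < 2) {
      stop("fewer than 2 pink-noise observations for topic ", tp)
    }
    data.frame(topic = tp, mu_pink = mean(pkrows), sigma_pink = sd(pkrows),
               degenerate = sd(pkrows) == 0, stringsAsFactors = FALSE)
  }))
  idx <- match(exam$topic, stats_df$topic)
  z <- (exam$keywords_correct - stats_df$mu_pink[idx]) / stats_df$sigma_pink[idx]
  z[stats_df$degenerate[idx]] <- NA_real_
  out <- exam
  out$z <- z
  attr(out, "pink_stats") <- stats_df
  out
}

#' Backward stepwise elimination by AIC
#'
#' Starting from the fitted (ML) model, repeatedly refits with each
#' single fixed term removed, drops the term whose removal lowers AIC
#' the most, and stops when no removal lowers AIC. Deterministic given
#' the data; works for both fixed (`lm`) and mixed (`lmer`) fits (the
#' random intercept is never a removal candidate).
#'
#' @param fit A `model_fit` fitted with `ml = TRUE`.
#' @param data Data used for the fit.
#' @return List with `fit` (the reduced `model_fit`), `retained` (fixed
#'   terms kept), and `path` (data frame of drops with AIC after each).
#' @export
stepwise_backward <- function(fit, data) {
  if (!fit$ml) stop("stepwise selection requires an ML fit")
  current <- fit
  path <- data.frame(dropped = character(0), AIC = numeric(0))
  repeat {
    ff <- if (current$mixed) lme4::nobars(current$formula) else current$formula
    terms_now <- attr(terms(ff), "term.labels")
    if (length(terms_now) == 0) break
    cand <- vapply(terms_now, function(tm) {
      f2 <- update(current$formula, paste0(". ~ . - ", tm))
      fit_lmm(f2, data)$AIC
    }, numeric(1))
    if (min(cand) >= current$AIC) break
    drop <- names(which.min(cand))
    current <- fit_lmm(update(current$formula, paste0(". ~ . - ", drop)), data)
    path <- rbind(path, data.frame(dropped = drop, AIC = current$AIC))
  }
  ff <- if (current$mixed) lme4::nobars(current$formula) else current$formula
  list(fit = current, retained = attr(terms(ff), "term.labels"), path = path)
}

#' Compare two fitted models
#'
#' Likelihood-ratio (chi-squared) test when the models are nested ML
#' fits on the same data, plus the AIC difference. For non-nested models
#' only the AIC difference is reported.
#'
#' @param fit_a,fit_b `model_fit` objects (order free; the smaller-edf
#'   model is treated as the null).
#' @return List with `chisq`, `df`, `p_value` (NA when not nested),
#'   `delta_aic` (`AIC(b) - AIC(a)` after ordering by edf), and
#'   `nested`.
#' @export
compare_models <- function(fit_a, fit_b) {
  if (fit_a$edf > fit_b$edf) {
    tmp <- fit_a
    fit_a <- fit_b
    fit_b <- tmp
  }
  ta <- attr(terms(if (fit_a$mixed) lme4::nobars(fit_a$formula) else fit_a$formula),
             "term.labels")
  tb <- attr(terms(if (fit_b$mixed) lme4::nobars(fit_b$formula) else fit_b$formula),
             "term.labels")
  nested <- all(ta %in% tb) && fit_a$ml && fit_b$ml
  delta_aic <- fit_b$AIC - fit_a$AIC
  if (!nested) {
    return(list(chisq = NA_real_, df = NA_integer_, p_value = NA_real_,
                delta_aic = delta_aic, nested = FALSE))
  }
  stat <- max(0, 2 * (fit_b$logLik - fit_a$logLik))
  df <- fit_b$edf - fit_a$edf
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(chisq = stat, df = df, p_value = p, delta_aic = delta_aic, nested = TRUE)
}

#' Predict exam z-scores from subregion-averaged component scores
#'
#' Builds the merged analysis table (one row per lecture fragment with
#' its exam z-score and the `k x 6` subregion-averaged PC scores as
#' predictors named `PCi_subregion`) and fits the model family: a
#' constant-only model, a background-type model, the full EEG model with
#' all predictors, and a backward-AIC stepwise reduction of the full
#' model. Fixed (`lm`) and mixed (participant random intercept) variants
#' are available.
#'
#' @param examz Exam table with `z` (see [exam_zscores()]).
#' @param subscores Subregion score table from [subregion_scores()]
#'   (lecture fragments).
#' @param mode `"fixed"` or `"mixed"`.
#' @param k Number of components used.
#' @return Object of class `exam_prediction`: list with `fits` (named
#'   `model_fit`s: constant, background, eeg_full, eeg_stepwise),
#'   `stepwise` (retained terms and path), `aic` (named vector),
#'   `comparisons` (LRT/AIC of the nested pairs), and `data`.
#' @export
predict_exam <- function(examz, subscores, mode = c("fixed", "mixed"), k = 9) {
  mode <- match.arg(mode)
  pcs <- paste0("PC", seq_len(k))
  wide <- stats::reshape(
    subscores[, c("participant", "topic", "background", "subregion", pcs)],
    direction = "wide", idvar = c("participant", "topic", "background"),
    timevar = "subregion", sep = "_"
  )
  names(wide) <- sub("^(PC[0-9]+)\\.(.*)$", "\\1_\\2", names(wide))
  dat <- merge(examz, wide, by = c("participant", "topic", "background"))
  dat <- dat[!is.na(dat$z), ]
  preds <- grep("^PC[0-9]+_", names(dat), value = TRUE)
  re <- if (mode == "mixed") " + (1 | participant)" else ""
  f_const <- as.formula(paste0("z ~ 1", re))
  f_bg <- as.formula(paste0("z ~ background", re))
  f_full <- as.formula(paste0("z ~ ", paste(preds, collapse = " + "), re))
  fits <- list(
    constant = fit_lmm(f_const, dat),
    background = fit_lmm(f_bg, dat),
    eeg_full = fit_lmm(f_full, dat)
  )
  sw <- stepwise_backward(fits$eeg_full, dat)
  fits$eeg_stepwise <- sw$fit
  comparisons <- list(
    background_vs_constant = compare_models(fits$constant, fits$background),
    eeg_full_vs_constant = compare_models(fits$constant, fits$eeg_full),
    eeg_stepwise_vs_constant = compare_models(fits$constant, fits$eeg_stepwise),
    eeg_full_vs_stepwise = compare_models(fits$eeg_stepwise, fits$eeg_full)
  )
  structure(
    list(fits = fits, stepwise = sw[c("retained", "path")],
         aic = vapply(fits, `[[`, numeric(1), "AIC"),
         comparisons = comparisons, data = dat, mode = mode, k = k),
    class = "exam_prediction"
  )
}

#' @export
print.exam_prediction <- function(x, ...) {
  cat(sprintf("<exam_prediction> mode %s, %d rows\n", x$mode, nrow(x$data)))
  print(round(x$aic, 2))
  cat("stepwise retained:", paste(x$stepwise$retained, collapse = ", "), "\n")
  invisible(x)
}
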
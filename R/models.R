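# Mixed-effects model stages: amplitude ~ driver and increment ~ rain, with
# by-tree random intercepts and slopes, likelihood-ratio model selection and
# marginal/conditional variance-explained reporting (lme4 backend).

fit_lmer_pair <- function(formula_full, data, diagonal = FALSE,
                          allow_fallback = TRUE) {
  # returns list(reml, ml, singular, diagonal); unless `diagonal` is forced,
  # falls back to a diagonal (||) random-effects covariance when the
  # unstructured fit is singular. Nested model pairs must share the same
  # structure, so the null of a pair is fitted with the full model's
  # `diagonal` outcome and fallback disabled.
  to_diag <- function(f) stats::as.formula(
    gsub("\\|", "||", paste(deparse(f), collapse = " ")))
  fml <- if (diagonal) to_diag(formula_full) else formula_full
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular && allow_fallback && !diagonal) {
    fml2 <- to_diag(formula_full)
    fit2 <- try(suppressMessages(suppressWarnings(
      lme4::lmer(fml2, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
      silent = TRUE)
    if (!inherits(fit2, "try-error")) { fit <- fit2; fml <- fml2; diagonal <- TRUE }
  }
  ml <- suppressMessages(suppressWarnings(lme4::refitML(fit)))
  list(reml = fit, ml = ml, formula = fml, singular = singular,
       diagonal = diagonal)
}

#' Marginal and conditional percent variance explained
#'
#' Decomposes the model variance into fixed-effect, random-effect and
#' residual components: the fixed component is the variance of the
#' fixed-effect predictor X beta across observations; the random component
#' is the mean of diag(Z Sigma Z') evaluated on the design (intercept and
#' slope components included); residual is sigma^2. Returns
#' 100 var_f / total and 100 (var_f + var_r) / total.
#'
#' @param fit a fitted `merMod`.
#' @return named numeric: `pct_fixed`, `pct_fixed_random`.
#' @export
variance_explained <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_f <- var(as.vector(X %*% lme4::fixef(fit)))
  Zt <- lme4::getME(fit, "Zt")
  Sigma <- stats::sigma(fit)^2 * Matrix::crossprod(lme4::getME(fit, "Lambdat"))
  var_r <- mean(Matrix::colSums(Zt * (Sigma %*% Zt)))
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  c(pct_fixed = 100 * var_f / tot,
    pct_fixed_random = 100 * (var_f + var_r) / tot)
}

#' Likelihood-ratio test between nested ML fits
#'
#' chi^2 = 2 (l_full - l_null), df = parameter-count difference, p from the
#' upper chi^2 tail. Both fits must be ML fits of the same data.
#'
#' @param m_null,m_full `merMod` objects fitted by maximum likelihood.
#' @return list `chisq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(m_null, m_full) {
  ll0 <- logLik(m_null); ll1 <- logLik(m_full)
  if (attr(ll0, "nobs") != attr(ll1, "nobs")) {
    stop("likelihood_ratio_test: models fitted to different data")
  }
  if (lme4::isREML(m_null) || lme4::isREML(m_full)) {
    stop("likelihood_ratio_test: fits must be ML, not REML")
  }
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df <= 0) stop("likelihood_ratio_test: models not nested (df difference <= 0)")
  chisq <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

model_fit_summary <- function(pair, data_n, n_groups) {
  fe <- lme4::fixef(pair$reml)
  se <- sqrt(Matrix::diag(stats::vcov(pair$reml)))
  pv <- variance_explained(pair$reml)
  list(formula = paste(deparse(pair$formula), collapse = " "),
       n_obs = data_n, n_groups = n_groups,
       fixed = tibble::tibble(term = names(fe), estimate = as.numeric(fe),
                              sd = as.numeric(se),
                              t = as.numeric(fe) / as.numeric(se)),
       logLik_ML = as.numeric(logLik(pair$ml)),
       logLik_REML = as.numeric(logLik(pair$reml)),
       AIC = AIC(pair$ml),
       pct_var_fixed = unname(pv["pct_fixed"]),
       pct_var_fixed_random = unname(pv["pct_fixed_random"]),
       singular = pair$singular,
       model = pair$reml, model_ml = pair$ml)
}

#' Mixed model for daily amplitude against one scaled driver
#'
#' Fits `A ~ x + (1 + x | tree)` (unstructured random intercept/slope;
#' diagonal fallback when singular) to, canonically, shrinking live trees on
#' rain-free days, against the null `A ~ 1 + (1 + x | tree)` that keeps the
#' full random structure but drops the fixed slope. REML estimates are
#' reported; the LRT uses ML refits.
#'
#' @param data tibble with columns `tree_id`, `A`, and the driver.
#' @param driver name of the (scaled) driver column.
#' @return list `full`, `null` (model summaries), `lrt` (chisq/df/p),
#'   `aic`, `aic_null`, `delta_aic` (null minus full, ML-based).
#' @export
fit_amplitude_mixed_model <- function(data, driver = "x") {
  d <- tibble::tibble(A = data$A, x = data[[driver]],
                      tree_id = factor(data$tree_id))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_tree <- nlevels(droplevels(d$tree_id))
  if (n_tree < 5 || nrow(d) / n_tree < 10) {
    warning("fit_amplitude_mixed_model: fewer than 5 trees or 10 days/tree")
  }
  if (var(d$x) == 0) stop("fit_amplitude_mixed_model: driver has zero variance")
  full <- fit_lmer_pair(A ~ x + (1 + x | tree_id), d)
  null <- fit_lmer_pair(A ~ 1 + (1 + x | tree_id), d,
                        diagonal = full$diagonal, allow_fallback = FALSE)
  lrt <- likelihood_ratio_test(null$ml, full$ml)
  list(full = model_fit_summary(full, nrow(d), n_tree),
       null = model_fit_summary(null, nrow(d), n_tree),
       lrt = lrt, aic = AIC(full$ml), aic_null = AIC(null$ml),
       delta_aic = AIC(null$ml) - AIC(full$ml))
}

#' Mixed models for the rain response of the daily increment
#'
#' Fits `I ~ rain + (1 + rain | tree)` and, optionally, variants adding bark
#' class and irrigation as fixed effects; all share the by-tree random
#' intercept and random rain slope. Candidates are compared to the constant
#' null (random structure retained) and to the rain-only model by LRT on ML
#' refits. The reported rain effect is the rainy-minus-rain-free difference
#' in I; the intercept is I on rain-free days.
#'
#' @param data tibble with `tree_id`, `I`, logical `rain`, and optionally
#'   `bark_class`, `irrigated`.
#' @param bark,irrigated include the corresponding fixed-effect variant.
#' @return list `models` (named summaries: null, rain, and variants),
#'   `lrt` (tibble of pairwise tests), `rain_effect`, `intercept` (each
#'   est/sd/t), `aic`, `aic_null`, `delta_aic`.
#' @export
fit_rain_mixed_model <- function(data, bark = FALSE, irrigated = FALSE) {
  d <- tibble::tibble(I = data$I, rain = as.logical(data$rain),
                      tree_id = factor(data$tree_id))
  if (bark) d$bark_class <- factor(data$bark_class)
  if (irrigated) d$irrigated <- as.logical(data$irrigated)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (length(unique(d$rain)) < 2) {
    stop("fit_rain_mixed_model: need both rainy and rain-free days")
  }
  one_state <- tapply(d$rain, d$tree_id, function(r) length(unique(r)) == 1)
  if (any(one_state, na.rm = TRUE)) {
    message(sprintf("fit_rain_mixed_model: %d tree(s) observed in only one rain state",
                    sum(one_state, na.rm = TRUE)))
  }
  n_tree <- nlevels(droplevels(d$tree_id))
  rain_full <- fit_lmer_pair(I ~ rain + (1 + rain | tree_id), d)
  dg <- rain_full$diagonal
  fits <- list(
    null = fit_lmer_pair(I ~ 1 + (1 + rain | tree_id), d,
                         diagonal = dg, allow_fallback = FALSE),
    rain = rain_full)
  if (bark) fits$rain_bark <-
    fit_lmer_pair(I ~ rain + bark_class + (1 + rain | tree_id), d,
                  diagonal = dg, allow_fallback = FALSE)
  if (irrigated) fits$rain_irrigated <-
    fit_lmer_pair(I ~ rain + irrigated + (1 + rain | tree_id), d,
                  diagonal = dg, allow_fallback = FALSE)
  lrt_rows <- list()
  for (nm in setdiff(names(fits), "null")) {
    lt <- likelihood_ratio_test(fits$null$ml, fits[[nm]]$ml)
    lrt_rows[[length(lrt_rows) + 1L]] <-
      tibble::tibble(model = nm, vs = "null", chisq = lt$chisq,
                     df = lt$df, p = lt$p)
    if (nm != "rain") {
      lt2 <- likelihood_ratio_test(fits$rain$ml, fits[[nm]]$ml)
      lrt_rows[[length(lrt_rows) + 1L]] <-
        tibble::tibble(model = nm, vs = "rain", chisq = lt2$chisq,
                       df = lt2$df, p = lt2$p)
    }
  }
  summaries <- lapply(fits, model_fit_summary, data_n = nrow(d),
                      n_groups = n_tree)
  fe <- summaries$rain$fixed
  rain_row <- fe[fe$term == "rainTRUE", , drop = FALSE]
  int_row <- fe[fe$term == "(Intercept)", , drop = FALSE]
  list(models = summaries, lrt = dplyr::bind_rows(lrt_rows),
       rain_effect = list(estimate = rain_row$estimate, sd = rain_row$sd,
                          t = rain_row$t),
       intercept = list(estimate = int_row$estimate, sd = int_row$sd,
                        t = int_row$t),
       aic = AIC(fits$rain$ml), aic_null = AIC(fits$null$ml),
       delta_aic = AIC(fits$null$ml) - AIC(fits$rain$ml))
}
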
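#' Random-intercept age-trajectory model for a per-scan quantity
#'
#' Fits `value ~ age + sex + site + (1 | subject)` by restricted maximum
#' likelihood, the model used for every per-scan quantity in the pipeline
#' (regional features, MSN weighted degree, structure-function coupling,
#' functional graph metrics). Age is centered at `baseline_age` (14 years by
#' default) internally, so the intercept is the predicted value at the start
#' of adolescence; t-statistics are unaffected by the centering.
#'
#' A factor (sex or site) with fewer than 2 observed levels is dropped from
#' the fixed effects automatically. Singular fits (subject variance at the
#' zero boundary) are retained at the boundary and flagged, never dropped;
#' with one scan per subject the boundary fit reproduces ordinary least
#' squares.
#'
#' @param table data.frame with columns `subject`, `age`, `sex`, `site` and
#'   the response.
#' @param response name of the response column (default "value").
#' @param baseline_age centering age in years.
#' @param df_method "residual" (t on `n_obs - n_fixed` df) or "satterthwaite"
#'   (requires the lmerTest package). The sample sizes in this design make
#'   the choice immaterial; residual is the default.
#' @return object of class `lme_fit`: list with `coef` (term, estimate, se,
#'   t, df, p), `beta_age`, `t_age`, `p_age`, `var_subject`, `var_resid`,
#'   `n_obs`, `n_subjects`, `singular`, `baseline` (see [predict_baseline()]),
#'   and the underlying `model` (a merMod).
#' @export
fit_lme <- function(table, response = "value", baseline_age = 14,
                    df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  stopifnot(all(c("subject", "age", "sex", "site") %in% names(table)),
            response %in% names(table))
  y <- table[[response]]
  if (!all(is.finite(y))) stop("response contains non-finite values")
  dat <- data.frame(value = y,
                    age_c = table$age - baseline_age,
                    sex = factor(table$sex), site = factor(table$site),
                    subject = factor(table$subject))
  terms <- "age_c"
  if (nlevels(dat$sex) >= 2) terms <- c(terms, "sex")
  if (nlevels(dat$site) >= 2) terms <- c(terms, "site")
  form <- stats::as.formula(
    paste("value ~", paste(terms, collapse = " + "), "+ (1 | subject)"))
  fit <- .quiet_lmer(form, dat, df_method)
  .summarize_lme(fit, dat, df_method, baseline_age)
}

.lmer_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.conv.singular = "ignore",
                    calc.derivs = FALSE)
}

.quiet_lmer <- function(form, dat, df_method) {
  fitter <- if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("df_method = 'satterthwaite' requires the lmerTest package")
    }
    lmerTest::lmer
  } else {
    lme4::lmer
  }
  suppressMessages(suppressWarnings(
    fitter(form, data = dat, REML = TRUE, control = .lmer_control())))
}

.summarize_lme <- function(fit, dat, df_method, baseline_age) {
  sm <- suppressMessages(suppressWarnings(summary(fit)))
  ct <- sm$coefficients
  est <- ct[, "Estimate"]
  se <- ct[, "Std. Error"]
  n_obs <- nrow(dat)
  n_fixed <- nrow(ct)
  if (df_method == "satterthwaite" && "df" %in% colnames(ct)) {
    dfree <- ct[, "df"]
    pval <- ct[, "Pr(>|t|)"]
    tval <- ct[, "t value"]
  } else {
    tval <- est / se
    dfree <- rep(n_obs - n_fixed, n_fixed)
    pval <- 2 * stats::pt(-abs(tval), dfree)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_subject <- vc$vcov[vc$grp == "subject"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  out <- list(
    coef = data.frame(term = rownames(ct), estimate = est, se = se,
                      t = tval, df = dfree, p = pval, row.names = NULL),
    beta_age = unname(est["age_c"]),
    se_age = unname(se["age_c"]),
    t_age = unname(tval[rownames(ct) == "age_c"]),
    p_age = unname(pval[rownames(ct) == "age_c"]),
    var_subject = var_subject,
    var_resid = var_resid,
    n_obs = n_obs,
    n_subjects = nlevels(dat$subject),
    singular = lme4::isSingular(fit),
    baseline_age = baseline_age,
    model = fit
  )
  class(out) <- "lme_fit"
  out$baseline <- predict_baseline(out)
  out
}

#' Predicted value at the baseline age
#'
#' Fixed-effects prediction at `baseline_age` (age centering makes this the
#' model intercept) with sex and site contributions averaged over their
#' observed level frequencies rather than fixed at a reference level, so the
#' baseline describes the cohort as sampled.
#'
#' @param fit an `lme_fit`.
#' @return scalar baseline prediction.
#' @export
predict_baseline <- function(fit) {
  stopifnot(inherits(fit, "lme_fit"))
  est <- fit$coef$estimate
  names(est) <- fit$coef$term
  base <- unname(est["(Intercept)"])
  mm <- stats::model.frame(fit$model)
  for (fac in c("sex", "site")) {
    if (!fac %in% names(mm)) next
    freqs <- table(mm[[fac]]) / nrow(mm)
    lv <- names(freqs)
    for (k in seq_along(lv)[-1]) {        # treatment coding: reference absorbed
      cn <- paste0(fac, lv[k])
      if (cn %in% names(est)) base <- base + est[[cn]] * freqs[[k]]
    }
  }
  unname(base)
}

#' Per-region age-effect map with FDR control
#'
#' Fits the random-intercept age model of [fit_lme()] to every region of a
#' scans x regions matrix, collects the age effect (estimate, t, p), adjusts
#' p-values across regions by Benjamini-Hochberg, and records the predicted
#' baseline at age 14. A global fit to the cortex-mean response is attached
#' as an attribute. For speed, the mixed model is fitted once and refitted
#' per region via [lme4::refit()].
#'
#' @param values numeric matrix, scans in rows, regions in columns.
#' @param meta data.frame aligned with rows: `subject`, `age`, `sex`, `site`.
#' @param baseline_age centering age.
#' @param df_method see [fit_lme()].
#' @param fdr_level significance level on q (default 0.05).
#' @return data.frame of class `age_effect_map` with columns `region`,
#'   `beta_age`, `se`, `t`, `p`, `q`, `baseline`, `singular`; attributes
#'   `global` (the cortex-mean `lme_fit`) and `fdr_level`.
#' @export
age_effect_map <- function(values, meta, baseline_age = 14,
                           df_method = c("residual", "satterthwaite"),
                           fdr_level = 0.05) {
  df_method <- match.arg(df_method)
  stopifnot(is.matrix(values), nrow(values) == nrow(meta))
  regions <- colnames(values)
  if (is.null(regions)) regions <- paste0("r", seq_len(ncol(values)))
  dat <- data.frame(value = values[, 1],
                    age_c = meta$age - baseline_age,
                    sex = factor(meta$sex), site = factor(meta$site),
                    subject = factor(meta$subject))
  terms <- "age_c"
  if (nlevels(dat$sex) >= 2) terms <- c(terms, "sex")
  if (nlevels(dat$site) >= 2) terms <- c(terms, "site")
  form <- stats::as.formula(
    paste("value ~", paste(terms, collapse = " + "), "+ (1 | subject)"))
  base_fit <- .quiet_lmer(form, dat, "residual")

  rows <- vector("list", ncol(values))
  for (j in seq_len(ncol(values))) {
    if (df_method == "satterthwaite") {
      dat$value <- values[, j]
      fj <- .quiet_lmer(form, dat, df_method)
    } else {
      fj <- tryCatch(
        suppressMessages(suppressWarnings(lme4::refit(base_fit, values[, j]))),
        error = function(e) NULL)
      if (is.null(fj)) {
        dat$value <- values[, j]
        fj <- .quiet_lmer(form, dat, "residual")
      }
    }
    sj <- .summarize_lme(fj, dat, df_method, baseline_age)
    rows[[j]] <- data.frame(region = regions[j], beta_age = sj$beta_age,
                            se = sj$se_age, t = sj$t_age, p = sj$p_age,
                            baseline = sj$baseline, singular = sj$singular,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("region", "beta_age", "se", "t", "p", "q", "baseline", "singular")]
  gdat <- data.frame(subject = meta$subject, age = meta$age, sex = meta$sex,
                     site = meta$site, value = rowMeans(values))
  attr(out, "global") <- fit_lme(gdat, baseline_age = baseline_age,
                                 df_method = df_method)
  attr(out, "fdr_level") <- fdr_level
  class(out) <- c("age_effect_map", "data.frame")
  out
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("lme_fit: %d obs, %d subjects%s\n", x$n_obs, x$n_subjects,
              if (x$singular) " (singular: subject variance at boundary)" else ""))
  print(x$coef, digits = 4)
  cat(sprintf("subject var %.4g, residual var %.4g, baseline(age %g) %.4g\n",
              x$var_subject, x$var_resid, x$baseline_age, x$baseline))
  invisible(x)
}
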
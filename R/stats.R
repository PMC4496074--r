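#' Specify a linear mixed model for a maze outcome
#'
#' The study's model family: a (possibly transformed) outcome with
#' handling method as a fixed effect, optional session term and
#' handling-by-session interaction for longitudinal outcomes, the
#' square-root of the stereotypy level as a covariate, and random
#' intercepts for litter and cage.
#'
#' @param outcome outcome column name.
#' @param fixed character vector of fixed-effect column names
#'   (default `"handling"`).
#' @param covariate column to enter as `sqrt(covariate)`, or `NULL`.
#'   The transform is applied exactly once: columns already named
#'   `sqrt_<x>` are rejected.
#' @param session session column for longitudinal models (entered as a
#'   continuous covariate), or `NULL`.
#' @param interaction include the handling-by-session interaction.
#' @param random grouping columns for random intercepts.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, fixed = "handling",
                       covariate = "stereotypy_level",
                       session = NULL, interaction = FALSE,
                       random = c("litter", "cage")) {
  if (!is.null(covariate) && startsWith(covariate, "sqrt_")) {
    stop("covariate '", covariate, "' appears to be already transformed; ",
         "pass the raw column (the sqrt transform is applied exactly once here)",
         call. = FALSE)
  }
  if (interaction && is.null(session)) {
    stop("interaction requires a session term", call. = FALSE)
  }
  structure(list(outcome = outcome, fixed = fixed, covariate = covariate,
                 session = session, interaction = interaction, random = random),
            class = "model_spec")
}

#' Fit the study's linear mixed model
#'
#' Fits the model described by a [model_spec()] with `lme4::lmer`
#' (REML), returning per-term F tests for the fixed effects. All model
#' terms here are single-degree-of-freedom, so each F statistic is the
#' squared Wald t of the term with a Satterthwaite-approximated
#' denominator df (computed from the REML deviance surface; see
#' `df_method`). Grouping factors with fewer than two levels (or at
#' least as many levels as observations) are dropped with a warning,
#' and grouping factors whose restricted LRT shows no evidence of
#' variance (see `keep_alpha`) are excluded and the model refitted —
#' retaining a spurious zero-boundary variance component only distorts
#' the small-sample inference; dropped factors are
#' recorded in `dropped`. With no random effects left the model
#' reduces to ordinary least squares, whose classical F tests are
#' reported. If a Satterthwaite df cannot be computed the residual df
#' is used, recorded per term in the `df_method` column. Factors are coded with sum-to-zero
#' contrasts so main-effect tests are Type-III-style in the presence of
#' an interaction.
#'
#' @param data per-mouse (or mouse-by-session) data.frame.
#' @param spec a `model_spec`.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @param keep_alpha retention level for random terms: a grouping
#'   factor stays in the model only if its restricted LRT against the
#'   reduced model has a boundary-mixture p-value below `keep_alpha`.
#'   Set to 1 to always keep all grouping factors.
#' @return object of class `mixed_fit`: `table` (term, estimate, se, F,
#'   df1, df2, p, df_method), `dropped` (dropped grouping factors),
#'   `singular`, `reml`, and the underlying `fit`.
#' @export
fit_mixed_model <- function(data, spec, df_method = c("satterthwaite", "residual"),
                            keep_alpha = 0.05) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  if (!spec$outcome %in% names(data)) {
    stop("outcome column '", spec$outcome, "' not found", call. = FALSE)
  }
  y <- data[[spec$outcome]]
  keep <- !is.na(y)
  terms_fixed <- spec$fixed
  if (!is.null(spec$covariate)) {
    tcol <- paste0("sqrt_", spec$covariate)
    data[[tcol]] <- sqrt(data[[spec$covariate]])
    terms_fixed <- c(terms_fixed, tcol)
  }
  if (!is.null(spec$session)) terms_fixed <- c(terms_fixed, spec$session)
  if (spec$interaction) {
    terms_fixed <- c(terms_fixed, paste0(spec$fixed[1], ":", spec$session))
    # centre the session covariate so the handling main effect is
    # evaluated at the mean session (Type-III-style)
    data[[spec$session]] <- data[[spec$session]] -
      mean(data[[spec$session]], na.rm = TRUE)
  }
  for (v in c(spec$fixed, spec$random)) {
    if (v %in% names(data) && !is.numeric(data[[v]])) {
      data[[v]] <- factor(data[[v]])
    }
  }
  keep <- keep & stats::complete.cases(data[, c(terms_fixed[!grepl(":", terms_fixed)],
                                                spec$random), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  data <- droplevels(data)
  constant <- stats::var(data[[spec$outcome]], na.rm = TRUE) == 0
  if (constant) {
    warning("outcome is constant; fit is degenerate", call. = FALSE)
  }

  dropped <- character(0)
  random <- spec$random
  for (g in spec$random) {
    nl <- length(unique(data[[g]]))
    if (nl < 2L || nl >= nrow(data)) {
      dropped <- c(dropped, g)
      random <- setdiff(random, g)
      warning("random-effect grouping '", g, "' has ", nl,
              " level(s); dropped from the model", call. = FALSE)
    }
  }

  rhs <- paste(terms_fixed, collapse = " + ")
  old_opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_opts), add = TRUE)

  ols_fit <- function() {
    fml <- stats::as.formula(paste(spec$outcome, "~", rhs))
    fit <- stats::lm(fml, data = data)
    structure(list(table = wald_table_lm(fit), dropped = dropped,
                   singular = FALSE, reml = FALSE, fit = fit, spec = spec),
              class = "mixed_fit")
  }
  if (length(random) == 0L || constant) return(ols_fit())

  # Random-effect retention: a grouping factor is kept only if it shows
  # evidence of explaining variance — a restricted LRT against the model
  # without it, referred to the 0.5*chi2(0) + 0.5*chi2(1) boundary
  # mixture. Factors with no effect are excluded and the model refitted
  # (the same practice as dropping cage/litter when they explain
  # nothing); dropped factors are recorded.
  fit_lmm <- function(rnd) {
    fml <- stats::as.formula(paste(
      spec$outcome, "~", rhs, "+",
      paste(sprintf("(1 | %s)", rnd), collapse = " + ")))
    lme4::lmer(fml, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  }
  reml_crit <- function(obj) -2 * stats::logLik(obj, REML = TRUE)[1]
  fit <- fit_lmm(random)
  keep <- vapply(random, function(g) {
    reduced <- if (length(random) > 1L) reml_crit(fit_lmm(setdiff(random, g)))
      else reml_crit(stats::lm(stats::as.formula(paste(spec$outcome, "~", rhs)),
                               data = data))
    stat <- max(0, reduced - reml_crit(fit))
    p_rlrt <- 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) +
      0.5 * (stat <= 0)
    p_rlrt < keep_alpha
  }, logical(1))
  if (!all(keep)) {
    dropped <- c(dropped, random[!keep])
    random <- random[keep]
    if (length(random) == 0L) return(ols_fit())
    fit <- fit_lmm(random)
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  tab <- wald_table_lmer(fit, df_method = df_method)
  structure(list(table = tab, dropped = dropped, singular = singular,
                 reml = TRUE, fit = fit, spec = spec),
            class = "mixed_fit")
}

# per-coefficient F table for an OLS fit (all non-intercept terms 1 df)
wald_table_lm <- function(fit) {
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             F = sm[, 3]^2, df1 = 1,
             df2 = stats::df.residual(fit),
             p = sm[, 4], df_method = "residual",
             row.names = NULL, stringsAsFactors = FALSE)
}

wald_table_lmer <- function(fit, df_method = "satterthwaite") {
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  idx <- which(names(beta) != "(Intercept)")
  n <- nrow(stats::model.frame(fit))
  p <- length(beta)
  df_resid <- n - p
  df2 <- rep(df_resid, length(idx))
  method <- rep("residual", length(idx))
  if (df_method == "satterthwaite") {
    sw <- tryCatch(satterthwaite_df(fit, idx), error = function(e) NULL)
    if (!is.null(sw)) {
      ok <- is.finite(sw) & sw > 0
      df2[ok] <- sw[ok]
      method[ok] <- "satterthwaite"
    }
  }
  tval <- beta[idx] / se[idx]
  data.frame(term = names(beta)[idx], estimate = unname(beta[idx]),
             se = unname(se[idx]), F = unname(tval^2), df1 = 1, df2 = df2,
             p = 2 * stats::pt(abs(tval), df2, lower.tail = FALSE),
             df_method = method, row.names = NULL, stringsAsFactors = FALSE)
}

#' Satterthwaite denominator degrees of freedom
#'
#' For each requested fixed-effect coefficient `l'beta` of a REML
#' `lmer` fit, approximates the denominator df as
#' `2 * (l' V l)^2 / Var(l' V l)`, where `V` is the covariance of the
#' fixed effects as a function of the variance parameters (random-effect
#' SDs and the residual SD), `Var(l' V l) = g' A g` with `g` the
#' gradient of `l' V l` at the REML estimate and `A` twice the inverse
#' Hessian of the REML deviance in the same parameterisation. Gradient
#' and Hessian are numerical (`numDeriv`). Errors (e.g. a singular
#' Hessian at a variance boundary) propagate to the caller, which falls
#' back to the residual df.
#'
#' @param fit an `lmerMod` fitted with REML.
#' @param idx integer indices of the fixed-effect coefficients.
#' @return numeric vector of dfs.
#' @keywords internal
satterthwaite_df <- function(fit, idx) {
  devfun <- lme4::lmer(stats::formula(fit), data = stats::model.frame(fit),
                       REML = TRUE, devFunOnly = TRUE)
  ee <- environment(devfun)
  np <- length(lme4::getME(fit, "theta"))
  n <- nrow(ee$pp$X)
  p <- ncol(ee$pp$X)
  sig <- stats::sigma(fit)
  vp_hat <- c(lme4::getME(fit, "theta") * sig, sig)

  dev_vp <- function(vp) {
    s <- vp[np + 1L]
    devfun(vp[seq_len(np)] / s)
    pwrss <- ee$resp$wrss() + ee$pp$sqrL(1)
    ee$pp$ldL2() + ee$pp$ldRX2() + (n - p) * log(2 * pi * s^2) + pwrss / s^2
  }
  vcov_fun <- function(vp) {
    s <- vp[np + 1L]
    devfun(vp[seq_len(np)] / s)
    s^2 * as.matrix(ee$pp$unsc())
  }

  H <- numDeriv::hessian(dev_vp, vp_hat)
  A <- 2 * solve(H)
  vapply(idx, function(i) {
    f <- function(vp) vcov_fun(vp)[i, i]
    g <- numDeriv::grad(f, vp_hat)
    denom <- drop(t(g) %*% A %*% g)
    if (denom <= 0) return(NA_real_)
    2 * f(vp_hat)^2 / denom
  }, numeric(1))
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit>%s%s\n",
              if (x$singular) " [singular]" else "",
              if (length(x$dropped))
                paste0(" [dropped: ", paste(x$dropped, collapse = ", "), "]")
              else ""))
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$df2 <- round(tab$df2, 1)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "estimate", "F", "df1", "df2", "p")], row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected paired t-tests for arm preferences
#'
#' Paired t statistic `mean(d) / (sd(d) / sqrt(n))` with `n - 1` df for
#' each declared contrast, Bonferroni-adjusted over the declared family
#' (`p_adj = min(1, p * n_contrasts)`).
#'
#' @param data wide per-mouse data.frame, one row per mouse.
#' @param contrasts named list; each element is `c(col_a, col_b)` and
#'   tests `col_a - col_b`.
#' @return data.frame of class `comparison_results`: `contrast`,
#'   `estimate` (mean difference), `t`, `df`, `p`, `p_adj`,
#'   `significant` (at 0.05).
#' @export
paired_arm_comparisons <- function(data, contrasts) {
  stopifnot(is.list(contrasts), length(contrasts) >= 1L,
            !is.null(names(contrasts)))
  m <- length(contrasts)
  rows <- lapply(names(contrasts), function(lbl) {
    cols <- contrasts[[lbl]]
    stopifnot(length(cols) == 2L)
    a <- data[[cols[1]]]; b <- data[[cols[2]]]
    ok <- !is.na(a) & !is.na(b)
    d <- a[ok] - b[ok]
    n <- length(d)
    if (n < 2L) stop("contrast '", lbl, "': fewer than 2 complete pairs",
                     call. = FALSE)
    sd_d <- stats::sd(d)
    tval <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
    p <- if (sd_d == 0 && mean(d) == 0) 1 else
      2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE)
    data.frame(contrast = lbl, estimate = mean(d), t = tval, df = n - 1L,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out$significant <- out$p_adj < 0.05
  class(out) <- c("comparison_results", "data.frame")
  out
}

#' Kruskal-Wallis test of stereotypy level by form
#'
#' Rank-based comparison of stereotypy levels across forms, computed
#' directly from the rank-sum formula with the tie correction
#' `C = 1 - sum(t^3 - t) / (N^3 - N)`. When all observations are tied
#' the statistic is 0 by convention (the uncorrected numerator is
#' already 0). df = number of groups - 1.
#'
#' @param levels numeric vector of stereotypy levels.
#' @param form group labels (at least two groups, each non-empty).
#' @return list of class `kw_test`: `statistic` (chi-square), `df`, `p`.
#' @export
stereotypy_form_test <- function(levels, form) {
  ok <- !is.na(levels) & !is.na(form)
  levels <- levels[ok]; form <- factor(form[ok])
  form <- droplevels(form)
  k <- nlevels(form)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  N <- length(levels)
  r <- rank(levels)
  Ri <- tapply(r, form, sum)
  ni <- tabulate(form)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(levels)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  stat <- if (C > 0) H / C else 0
  structure(list(statistic = stat, df = k - 1L,
                 p = stats::pchisq(stat, k - 1L, lower.tail = FALSE)),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("<kw_test> chi-square(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p))
  invisible(x)
}
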
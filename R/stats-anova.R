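#' Mixed-effects ANOVA of stimulation effects
#'
#' Fits a linear mixed-effects model of per-cell effects with cell group,
#' condition and pure-tone frequency as crossed fixed factors (all
#' interactions up to three-way) and field of view as a random intercept,
#' then computes type III F-tests with sum-to-zero factor coding
#' (Satterthwaite denominator degrees of freedom). If the random-intercept
#' fit is singular the model falls back to a fixed-FOV-effect linear model
#' with type III tests, with a warning.
#'
#' @param data data.frame of the effect table.
#' @param response response column name, default `"effect"`.
#' @param fixed character vector of fixed-factor column names, default
#'   `c("group", "condition", "tone_khz")`.
#' @param random grouping column for the random intercept, default `"fov"`.
#' @return an `anova_result`: `terms` (data.frame with F, df1, df2, p),
#'   `model`, `method` (`"lmer-satterthwaite"` or `"lm-fixed-fov"`),
#'   `singular` flag.
#' @export
fit_mixed_anova <- function(data, response = "effect",
                            fixed = c("group", "condition", "tone_khz"),
                            random = "fov") {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(fixed %in% names(data)), random %in% names(data))
  df <- data[stats::complete.cases(data[c(response, fixed, random)]), ]
  for (f in c(fixed, random)) {
    df[[f]] <- factor(df[[f]])
    if (f %in% fixed && nlevels(df[[f]]) < 2L)
      stop("fixed factor '", f, "' has fewer than 2 levels")
  }
  if (nlevels(df[[random]]) < 2L)
    stop("need at least 2 levels of '", random, "'")
  contr <- stats::setNames(rep(list("contr.sum"), length(fixed)), fixed)
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " * "),
    "+ (1 |", random, ")"))
  fit <- tryCatch(
    lmerTest::lmer(fml, data = df, contrasts = contr),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit)
  if (!singular) {
    at <- as.data.frame(stats::anova(fit, type = 3))
    terms <- data.frame(term = rownames(at), F = at[["F value"]],
                        df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                        p = at[["Pr(>F)"]], row.names = NULL)
    method <- "lmer-satterthwaite"
  } else {
    warning("singular random-intercept fit; falling back to a fixed-",
            random, "-effect model")
    if (!requireNamespace("car", quietly = TRUE))
      stop("the fallback fixed-effect ANOVA requires the 'car' package")
    fml2 <- stats::as.formula(paste(
      response, "~", paste(fixed, collapse = " * "), "+", random))
    contr2 <- c(contr, stats::setNames(list("contr.sum"), random))
    fit <- stats::lm(fml2, data = df, contrasts = contr2)
    at <- tryCatch(as.data.frame(car::Anova(fit, type = 3)),
                   error = function(e) NULL)
    method <- "lm-fixed-fov"
    if (is.null(at)) {
      # grouping factor aliased with a between-FOV fixed factor: drop it
      fml2 <- stats::as.formula(paste(
        response, "~", paste(fixed, collapse = " * ")))
      fit <- stats::lm(fml2, data = df, contrasts = contr)
      at <- tryCatch(as.data.frame(car::Anova(fit, type = 3)),
                     error = function(e) NULL)
      method <- "lm-no-fov"
    }
    if (is.null(at)) {
      # e.g. an exactly constant response: no variance left to test
      trm <- attr(stats::terms(fml2), "term.labels")
      return(structure(list(
        terms = data.frame(term = trm, F = NA_real_, df1 = NA_real_,
                           df2 = NA_real_, p = NA_real_),
        model = fit, method = "degenerate", singular = TRUE,
        formula = deparse(fml), data = df), class = "anova_result"))
    }
    keep <- !rownames(at) %in% c("(Intercept)", "Residuals", random)
    terms <- data.frame(term = rownames(at)[keep],
                        F = at[["F value"]][keep], df1 = at$Df[keep],
                        df2 = at$Df[rownames(at) == "Residuals"],
                        p = at[["Pr(>F)"]][keep], row.names = NULL)
  }
  structure(list(terms = terms, model = fit, method = method,
                 singular = singular,
                 formula = deparse(fml), data = df),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, digits = 4, ...) {
  cat("<anova_result> type III tests (", x$method, ")\n", sep = "")
  tt <- x$terms
  tt$F <- signif(tt$F, digits)
  tt$df2 <- signif(tt$df2, digits)
  tt$p <- signif(tt$p, digits)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Estimated-marginal-means contrasts
#'
#' Post hoc condition contrasts on a fitted model: estimated marginal means
#' per factor cell, pairwise condition comparisons within each group x tone
#' cell, Tukey-adjusted p-values.
#'
#' @param fit an `anova_result` (or a model accepted by
#'   [emmeans::emmeans()]).
#' @param specs emmeans specification, default
#'   `~ condition | group * tone_khz`.
#' @param adjust multiplicity adjustment for the pairwise contrasts,
#'   default `"tukey"`.
#' @return list with `emmeans` and `contrasts` data.frames (inestimable
#'   contrasts carry NA estimates).
#' @export
emm_contrasts <- function(fit, specs = ~ condition | group * tone_khz,
                          adjust = "tukey") {
  model <- if (inherits(fit, "anova_result")) fit$model else fit
  em <- emmeans::emmeans(model, specs,
                         lmer.df = "satterthwaite",
                         lmerTest.limit = 1e6)
  prs <- emmeans::contrast(em, method = "pairwise", adjust = adjust)
  list(emmeans = as.data.frame(em), contrasts = as.data.frame(prs))
}

#' Selectivity-tertile post hoc comparisons
#'
#' Within each cell group and selectivity bin, pairwise Welch t-tests of the
#' effect between conditions, Holm-Bonferroni adjusted within each
#' group x bin family. Bins observed under fewer than two conditions are
#' skipped (noted in the result).
#'
#' @param data effect-table data.frame.
#' @param value effect column, default `"effect"`.
#' @param group,bin,condition factor column names.
#' @return data.frame: group, bin, pair, estimate (condition difference),
#'   t, df, p, p_holm; skipped bins carry NA statistics.
#' @export
tertile_posthoc <- function(data, value = "effect", group = "group",
                            bin = "selectivity_bin",
                            condition = "condition") {
  stopifnot(all(c(value, group, bin, condition) %in% names(data)))
  data <- data[!is.na(data[[bin]]) & data[[bin]] != "excluded_outlier", ]
  out <- list()
  for (g in unique(data[[group]])) {
    for (b in intersect(c("low", "mid", "high"),
                        unique(data[[bin]][data[[group]] == g]))) {
      sub <- data[data[[group]] == g & data[[bin]] == b, ]
      conds <- sort(unique(as.character(sub[[condition]])))
      if (length(conds) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, bin = b, pair = NA_character_, estimate = NA_real_,
          t = NA_real_, df = NA_real_, p = NA_real_, p_holm = NA_real_,
          note = "skipped: single condition")
        next
      }
      rows <- list()
      for (i in seq_len(length(conds) - 1L)) for (j in (i + 1):length(conds)) {
        x <- sub[[value]][sub[[condition]] == conds[i]]
        y <- sub[[value]][sub[[condition]] == conds[j]]
        tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          # degenerate comparison: identical constants are a sure null
          list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
        } else stats::t.test(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, bin = b, pair = paste(conds[i], "-", conds[j]),
          estimate = mean(x) - mean(y), t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value, p_holm = NA_real_,
          note = "")
      }
      fam <- do.call(rbind, rows)
      fam$p_holm <- stats::p.adjust(fam$p, method = "holm")
      out[[length(out) + 1L]] <- fam
    }
  }
  do.call(rbind, out)
}
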
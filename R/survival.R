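#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow handling of tied event times,
#' standard errors from the inverse observed information, and two-sided
#' normal p-values on `z = beta / SE`. Non-convergence and separation
#' (`|beta|` exceeding 10) are flagged, never silent.
#'
#' @param x covariate matrix (samples x covariates) or a numeric vector.
#' @param time survival times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return list of class `coxFit`: `beta`, `se`, `z`, `p`, `loglik`,
#'   `converged`, `separated`, `fit` (the underlying model object).
#' @export
coxFit <- function(x, time, event) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(time) == nrow(x), length(event) == nrow(x), all(time > 0))
  if (sum(event) < 1) stop("at least one event is required")
  if (any(apply(x, 2L, function(v) stats::sd(v) == 0)))
    stop("constant covariate: coefficient not identifiable")
  dat <- data.frame(.time = time, .event = event, x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|iterations", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (anyNA(beta)) converged <- FALSE
  structure(list(beta = beta, se = se, z = beta / se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = converged,
                 separated = any(abs(beta) > 10, na.rm = TRUE),
                 fit = fit),
            class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat("Cox fit (Breslow ties):\n")
  print(data.frame(beta = x$beta, se = x$se, z = x$z, p = x$p))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  if (x$separated) cat("WARNING: possible separation (|beta| > 10)\n")
  invisible(x)
}

#' Univariate Cox screen over genes
#'
#' Fits one single-covariate Cox model per gene, BH-adjusts the p-values
#' across all genes, and retains genes with `q < qThreshold` (strict). Genes
#' whose fit fails, does not converge, or separates are excluded with a
#' warning.
#'
#' @param expr gene x sample expression matrix.
#' @param time,event per-sample survival data (columns of `expr`).
#' @param qThreshold BH q-value cut-off (default 0.1).
#' @return `data.frame` with `geneId`, `beta`, `se`, `z`, `p`, `q`,
#'   `retained`.
#' @export
univariateScreen <- function(expr, time, event, qThreshold = 0.1) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) >= 1L, ncol(expr) == length(time))
  rows <- lapply(rownames(expr), function(g) {
    f <- tryCatch(coxFit(expr[g, ], time, event), error = function(e) NULL)
    if (is.null(f) || !f$converged || f$separated)
      return(data.frame(geneId = g, beta = NA_real_, se = NA_real_,
                        z = NA_real_, p = NA_real_))
    data.frame(geneId = g, beta = unname(f$beta), se = unname(f$se),
               z = unname(f$z), p = unname(f$p))
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$p))
    warning(sum(is.na(out$p)), " gene(s) excluded from the screen ",
            "(failed, non-converged or separated fits)")
  out$q <- adjustBH(out$p)
  out$retained <- !is.na(out$q) & out$q < qThreshold
  out
}

#' Build a Cox risk-score signature
#'
#' From the univariate screen survivors, keeps the `signatureSize` genes with
#' the largest univariate `|z|` (a deterministic feature-reduction rule),
#' fits one multivariate Cox model on them, and stores its coefficients
#' together with the training-median risk score as the high/low threshold.
#' Returns `NULL` (with a message) when the screen retains nothing — the
#' "no signature" outcome.
#'
#' @inheritParams univariateScreen
#' @param signatureSize number of genes kept (default 6).
#' @param screen optional precomputed [univariateScreen()] result.
#' @return a [CoxRiskModel-class], or `NULL` when no gene passes the screen.
#' @export
buildRiskModel <- function(expr, time, event, signatureSize = 6,
                           qThreshold = 0.1, screen = NULL) {
  expr <- as.matrix(expr)
  if (is.null(screen)) screen <- univariateScreen(expr, time, event, qThreshold)
  kept <- screen[screen$retained, ]
  if (nrow(kept) == 0L) {
    message("no gene passed the univariate screen: no signature")
    return(NULL)
  }
  kept <- kept[order(-abs(kept$z)), ]
  sel <- utils::head(kept$geneId, signatureSize)
  mfit <- coxFit(t(expr[sel, , drop = FALSE]), time, event)
  if (!mfit$converged)
    stop("multivariate Cox fit did not converge for the selected signature")
  risk <- as.numeric(crossprod(expr[sel, , drop = FALSE], mfit$beta))
  if (stats::sd(risk) == 0)
    stop("degenerate risk scores (all equal): median split undefined")
  new("CoxRiskModel", geneIds = sel, beta = unname(mfit$beta),
      threshold = stats::median(risk), fit = mfit)
}

#' Per-sample risk scores under a risk model
#'
#' `risk_j = sum_i x_ij * beta_i` over the signature genes.
#'
#' @param model a [CoxRiskModel-class].
#' @param expr gene x sample expression matrix containing the signature genes.
#' @return named numeric vector of risk scores.
#' @export
riskScores <- function(model, expr) {
  expr <- as.matrix(expr)
  miss <- setdiff(model@geneIds, rownames(expr))
  if (length(miss)) stop("signature gene(s) missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  stats::setNames(
    as.numeric(crossprod(expr[model@geneIds, , drop = FALSE], model@beta)),
    colnames(expr))
}

#' High/low risk groups by the training median
#'
#' Samples with risk score strictly above the training-median threshold are
#' "high"; scores at or below it (including exact ties with the median) are
#' "low".
#'
#' @inheritParams riskScores
#' @return factor with levels `low`, `high`.
#' @export
riskGroups <- function(model, expr) {
  rs <- riskScores(model, expr)
  factor(ifelse(rs > model@threshold, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the standard log-rank
#' chi-square (hypergeometric variance) with a 1-df chi-square p-value. With
#' no events anywhere the statistic is undefined; `chisq = 0`, `p = 1` is
#' returned with a warning.
#'
#' @param groups two-level factor per sample.
#' @param time,event survival data.
#' @return list with `fit` (a `survfit` object), `chisq`, `p`.
#' @export
kmLogrank <- function(groups, time, event) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two non-empty groups required")
  dat <- data.frame(time = time, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  if (sum(event) == 0) {
    warning("no events in either group: log-rank undefined, returning p = 1")
    return(list(fit = fit, chisq = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chisq <- unname(sd$chisq)
  list(fit = fit, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
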
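#' Linear generalized estimating equations for clustered eyes
#'
#' Fits a marginal linear model (identity link, Gaussian variance) by
#' generalized estimating equations with an exchangeable working correlation
#' across eyes of the same subject, and reports robust (sandwich) standard
#' errors. This is the standard model for ocular data where both eyes of a
#' subject enter the sample and are correlated. With
#' `corstr = "independence"` the coefficients reduce to ordinary least
#' squares while the robust cluster sandwich is retained.
#'
#' Inference is Wald: 95% confidence intervals and two-sided p-values use
#' the normal reference distribution on the robust standard errors, with no
#' small-sample correction.
#'
#' @param formula model formula, e.g. `onhv_mm3 ~ icp_cmH2O` or
#'   `onhv_mm3 ~ icp_cmH2O + gccv_mm3`.
#' @param data a data frame (e.g. an `onh_cohort` from [simulate_cohort()]).
#' @param id cluster identifier: a column name (bare or character) in `data`,
#'   default `subject_id`.
#' @param corstr working correlation structure, `"exchangeable"` (default)
#'   or `"independence"`.
#' @param maxit,tol iteration control for the coefficient/correlation
#'   updates.
#' @return An object of class `gee_lm` with methods `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `predict`, `fitted`, `residuals`.
#' @examples
#' tab <- simulate_cohort(cohort_params(n_subjects = 40, seed = 1))
#' fit <- gee_lm(onhv_mm3 ~ icp_cmH2O, tab)
#' summary(fit)
#' @export
gee_lm <- function(formula, data, id = subject_id,
                   corstr = c("exchangeable", "independence"),
                   maxit = 50L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  cl <- match.call()
  id <- eval(substitute(id), data, parent.frame())
  if (is.character(id) && length(id) == 1L && id %in% names(data))
    id <- data[[id]]
  if (length(id) != nrow(data)) stop("id must index every row of data")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  id <- factor(id)
  if (nlevels(id) < 2L) stop("need at least 2 clusters")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  n <- length(y); p <- ncol(X)
  groups <- split(seq_len(n), id)

  beta <- stats::lm.fit(X, y)$coefficients
  alpha <- 0
  for (iter in seq_len(maxit)) {
    e <- y - drop(X %*% beta)
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (g in groups) {
        ng <- length(g)
        if (ng > 1L) {
          s <- sum(e[g])^2 - sum(e[g]^2)
          num <- num + s / 2
          npairs <- npairs + ng * (ng - 1) / 2
        }
      }
      alpha <- if (phi > 0 && npairs > p) num / phi / (npairs - p) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (g in groups) {
      ng <- length(g)
      Rinv <- if (ng == 1L || alpha == 0) diag(1, ng) else
        solve((1 - alpha) * diag(ng) + alpha * matrix(1, ng, ng))
      Xg <- X[g, , drop = FALSE]
      A <- A + crossprod(Xg, Rinv %*% Xg)
      b <- b + crossprod(Xg, Rinv %*% y[g])
    }
    beta_new <- drop(solve(A, b))
    done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))
    beta <- beta_new
    if (done) break
  }
  e <- y - drop(X %*% beta)
  # robust sandwich: bread = model-based information, meat = empirical
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in groups) {
    ng <- length(g)
    Rinv <- if (ng == 1L || alpha == 0) diag(1, ng) else
      solve((1 - alpha) * diag(ng) + alpha * matrix(1, ng, ng))
    Xg <- X[g, , drop = FALSE]
    XtR <- crossprod(Xg, Rinv)
    A <- A + XtR %*% Xg
    u <- XtR %*% e[g]
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  vcov_robust <- Ainv %*% B %*% Ainv
  phi <- sum(e^2) / (n - p)
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         vcov = vcov_robust, naive_vcov = phi * Ainv,
         alpha = alpha, phi = phi, corstr = corstr,
         fitted.values = drop(X %*% beta), residuals = e,
         n_obs = n, n_clusters = length(groups),
         formula = formula, terms = attr(mf, "terms"),
         xlevels = stats::.getXlevels(attr(mf, "terms"), mf), call = cl),
    class = "gee_lm")
}

#' @export
coef.gee_lm <- function(object, ...) object$coefficients

#' @export
vcov.gee_lm <- function(object, ...) object$vcov

#' @export
fitted.gee_lm <- function(object, ...) object$fitted.values

#' @export
residuals.gee_lm <- function(object, ...) object$residuals

#' @export
confint.gee_lm <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  dimnames(ci) <- list(names(cf),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.gee_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% coef(object))
}

#' @export
print.gee_lm <- function(x, ...) {
  cat(sprintf("Linear GEE (%s working correlation), %d eyes in %d subjects\n",
              x$corstr, x$n_obs, x$n_clusters))
  cat("Call: "); print(x$call)
  cat("\nCoefficients:\n"); print(x$coefficients)
  if (x$corstr == "exchangeable")
    cat(sprintf("\nEstimated within-subject correlation: %.3f\n", x$alpha))
  invisible(x)
}

#' @export
summary.gee_lm <- function(object, ...) {
  tab <- model_terms(object)
  structure(list(fit = object, terms = tab), class = "summary.gee_lm")
}

#' @export
print.summary.gee_lm <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Linear GEE (%s working correlation), robust SEs\n%d eyes in %d subjects; scale %.4f",
              f$corstr, f$n_obs, f$n_clusters, f$phi))
  if (f$corstr == "exchangeable")
    cat(sprintf("; within-subject correlation %.3f", f$alpha))
  cat("\n\n")
  tt <- x$terms
  out <- data.frame(Estimate = tt$coefficient,
                    `Robust SE` = tt$se,
                    `95% CI` = sprintf("(%.3f, %.3f)", tt$ci_low, tt$ci_high),
                    `p` = format.pval(tt$p_value, digits = 3),
                    check.names = FALSE, row.names = tt$term)
  print(out, digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted association model
#'
#' Uniform extraction of (term, coefficient, robust/OLS standard error,
#' Wald 95% CI, two-sided p) from [gee_lm()] and [one_eye_lm()] fits —
#' the layout of a clinical coefficients table.
#'
#' @param fit a `gee_lm` or `one_eye_lm` object.
#' @param level confidence level, default 0.95.
#' @return data frame with columns `term`, `coefficient`, `se`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
model_terms <- function(fit, level = 0.95) UseMethod("model_terms")

#' @export
model_terms.gee_lm <- function(fit, level = 0.95) {
  cf <- coef(fit)
  se <- sqrt(diag(fit$vcov))
  z <- ifelse(se > 0, cf / se, ifelse(cf == 0, 0, Inf))
  q <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(cf), coefficient = unname(cf), se = unname(se),
             ci_low = unname(cf - q * se), ci_high = unname(cf + q * se),
             p_value = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Select one eye per subject (right eye unless only the left is present)
#'
#' @param data data frame with `subject_id` and `eye` ("OD"/"OS") columns.
#' @return the subset with one row per subject.
#' @export
select_one_eye <- function(data) {
  stopifnot(all(c("subject_id", "eye") %in% names(data)))
  keep <- unlist(lapply(split(seq_len(nrow(data)), data$subject_id),
                        function(idx) {
    od <- idx[data$eye[idx] == "OD"]
    if (length(od)) od[1] else idx[1]
  }), use.names = FALSE)
  data[sort(keep), , drop = FALSE]
}

#' One-eye-per-subject linear regression with Pearson correlation
#'
#' Repeats an association analysis using one eye per subject (right eye
#' unless only one eye is available) and ordinary least squares, reporting
#' t-based 95% CIs and the Pearson correlation between outcome and
#' prediction (for a single predictor this is the plain Pearson r, signed by
#' the slope).
#'
#' @param formula model formula (outcome ~ predictors).
#' @param data data frame with `subject_id` and `eye` columns.
#' @return An object of class `one_eye_lm`: the underlying `lm` in `$fit`,
#'   the Pearson correlation in `$r`, the retained data in `$data`.
#' @export
one_eye_lm <- function(formula, data) {
  one <- select_one_eye(data)
  if (nrow(one) < 3L) stop("need at least 3 subjects after eye selection")
  fit <- stats::lm(formula, data = one)
  y <- stats::model.response(stats::model.frame(fit))
  r <- suppressWarnings(stats::cor(y, stats::fitted(fit)))
  # multiple correlation is non-negative; sign by the slope when univariable
  cf <- stats::coef(fit)
  if (length(cf) == 2L && is.finite(cf[2])) r <- abs(r) * sign(cf[2])
  structure(list(fit = fit, r = unname(r), data = one, formula = formula),
            class = "one_eye_lm")
}

#' @export
coef.one_eye_lm <- function(object, ...) stats::coef(object$fit)

#' @export
confint.one_eye_lm <- function(object, ...) stats::confint(object$fit, ...)

#' @export
model_terms.one_eye_lm <- function(fit, level = 0.95) {
  sm <- summary(fit$fit)$coefficients
  ci <- stats::confint(fit$fit, level = level)
  data.frame(term = rownames(sm), coefficient = unname(sm[, 1]),
             se = unname(sm[, 2]),
             ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
             p_value = unname(sm[, 4]), stringsAsFactors = FALSE)
}

#' @export
print.one_eye_lm <- function(x, ...) {
  cat(sprintf("One-eye OLS (%d subjects), Pearson r = %.3f\n",
              nrow(x$data), x$r))
  print(model_terms(x), digits = 4)
  invisible(x)
}

#' Pearson correlation between two cohort variables
#'
#' @param data data frame.
#' @param var_a,var_b column names.
#' @param one_eye if `TRUE` (default), restrict to one eye per subject via
#'   [select_one_eye()] first.
#' @return list with `rho`, `p_value`, `n`.
#' @export
pairwise_correlation <- function(data, var_a, var_b, one_eye = TRUE) {
  if (one_eye) data <- select_one_eye(data)
  a <- data[[var_a]]; b <- data[[var_b]]
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in ", if (stats::sd(a) == 0) var_a else var_b)
  ct <- stats::cor.test(a, b, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
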
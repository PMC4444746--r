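#' Pilocarpine-stimulated salivary flow model Q(t) = A * t^B + C
#'
#' Salivary flow in pilocarpine-infused rats rises dynamically from a
#' baseline; the three-constant power law `Q(t) = A * t^B + C` (mL/h, t in
#' h) captures this. `C` is the baseline flow, `A` and `B` shape the
#' stimulated component.
#'
#' @param A Stimulated-flow coefficient, mL/h per h^B. `A >= 0`.
#' @param B Dimensionless exponent, `B > -1`.
#' @param C Baseline flow, mL/h, `C >= 0`.
#' @return An object of class `"flow_model"`.
#' @examples
#' fm <- flow_model(2, 0.5, 1)
#' flow_rate(4, fm)  # 2 * 2 + 1 = 5 mL/h
#' @export
flow_model <- function(A, B, C) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C))
  if (A < 0) stop("A must be nonnegative", call. = FALSE)
  if (B <= -1) stop("B must exceed -1 (integrable flow)", call. = FALSE)
  if (C < 0) stop("baseline flow C must be nonnegative", call. = FALSE)
  structure(list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C)),
            class = "flow_model")
}

#' @rdname flow_model
#' @param x A `flow_model`.
#' @param ... Unused.
#' @export
print.flow_model <- function(x, ...) {
  cat("<flow_model> Q(t) = ", format(x$A), " * t^", format(x$B), " + ",
      format(x$C), "  [mL/h, t in h]\n", sep = "")
  invisible(x)
}

#' @rdname flow_model
#' @param t Time(s), h, `t >= 0`. For `B < 0` the power term is singular at
#'   `t = 0`; the value is guarded to the baseline `C` with a warning.
#' @param flow A `flow_model`.
#' @export
flow_rate <- function(t, flow) {
  stopifnot(inherits(flow, "flow_model"), is.numeric(t), all(is.finite(t)),
            all(t >= 0))
  q <- numeric(length(t))
  at0 <- t == 0
  if (any(at0)) {
    if (flow$B < 0 && flow$A > 0) {
      warning("Q(t): power term singular at t = 0 (B < 0); returning ",
              "baseline C there", call. = FALSE)
      q[at0] <- flow$C
    } else if (flow$B == 0) {
      q[at0] <- flow$A + flow$C
    } else {
      q[at0] <- flow$C
    }
  }
  q[!at0] <- flow$A * t[!at0]^flow$B + flow$C
  q
}

#' Fit the salivary flow model to measured flow data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of
#' `Q(t) = A * t^B + C` to observed salivary flow-rate measurements, as
#' collected from pilocarpine-infused rats. Bounds: `A >= 0`,
#' `B` in (-0.99, 3], `C >= 0`. Multiple starting exponents are tried and
#' the best residual sum of squares kept. Residuals are additive by
#' default; `multiplicative = TRUE` fits on the log scale instead
#' (appropriate when measurement error scales with flow).
#'
#' @param times Observation times, h, `>= 0`; at least 4 observations.
#' @param flows Measured flow rates, mL/h, positive.
#' @param multiplicative Logical; fit log(flow) instead of flow.
#' @return An object of class `"flow_fit"`: the fitted [flow_model()] plus
#'   estimates, residual sum of squares, convergence flag, and the data.
#'   Supports `coef()`, `predict()`, `residuals()`, `fitted()`, `print()`
#'   and `summary()`.
#' @examples
#' t <- seq(0.25, 4, length.out = 16)
#' fit <- fit_flow_model(t, 2 * sqrt(t) + 1)
#' coef(fit)  # recovers A = 2, B = 0.5, C = 1
#' @export
fit_flow_model <- function(times, flows, multiplicative = FALSE) {
  stopifnot(is.numeric(times), is.numeric(flows),
            length(times) == length(flows))
  if (length(times) < 4L) {
    stop("need at least 4 observations to fit (A, B, C)", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and nonnegative", call. = FALSE)
  }
  if (any(!is.finite(flows)) || any(flows < 0)) {
    stop("flows must be finite and nonnegative", call. = FALSE)
  }
  if (multiplicative && any(flows <= 0)) {
    stop("multiplicative residuals require strictly positive flows",
         call. = FALSE)
  }

  qfun <- function(p, t) {
    q <- p[1] * t^p[2] + p[3]
    # guard the t = 0 singularity for negative exponents during search
    q[t == 0] <- if (p[2] >= 0) p[1] * (t[t == 0]^p[2]) + p[3] else p[3]
    q
  }
  resid_fun <- function(p) {
    pred <- qfun(p, times)
    if (multiplicative) log(pmax(pred, 1e-12)) - log(flows)
    else pred - flows
  }

  lower <- c(A = 0, B = -0.99, C = 0)
  upper <- c(A = Inf, B = 3, C = Inf)
  c0 <- max(min(flows), 1e-8)
  a0 <- max(max(flows) - c0, 1e-8) / max(max(times), 1)^0.5
  best <- NULL
  for (b0 in c(0.2, 0.5, 1, 1.5)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(A = a0, B = b0, C = c0), fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("flow-model fit failed to converge from every starting point",
         call. = FALSE)
  }
  fit <- best$fit
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("flow-model fit did not converge (nls.lm info = ", fit$info,
            "): ", fit$message, call. = FALSE)
  }
  est <- stats::coef(fit)
  structure(
    list(model = flow_model(est[["A"]], est[["B"]], est[["C"]]),
         coefficients = est, rss = best$rss, converged = converged,
         info = fit$info, message = fit$message,
         multiplicative = multiplicative,
         data = data.frame(times = times, flows = flows)),
    class = "flow_fit"
  )
}

#' @rdname fit_flow_model
#' @param object,x A `flow_fit`.
#' @param ... Unused.
#' @export
coef.flow_fit <- function(object, ...) object$coefficients

#' @rdname fit_flow_model
#' @param newdata Optional numeric vector of times (h) at which to predict.
#' @export
predict.flow_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$times else newdata
  flow_rate(t, object$model)
}

#' @rdname fit_flow_model
#' @export
fitted.flow_fit <- function(object, ...) predict(object)

#' @rdname fit_flow_model
#' @export
residuals.flow_fit <- function(object, ...) {
  if (object$multiplicative) log(object$data$flows) - log(fitted(object))
  else object$data$flows - fitted(object)
}

#' @rdname fit_flow_model
#' @export
print.flow_fit <- function(x, ...) {
  cat("<flow_fit> Q(t) = A * t^B + C",
      if (x$multiplicative) " (multiplicative residuals)", "\n", sep = "")
  print(round(x$coefficients, 6))
  cat("RSS ", format(x$rss, digits = 6), " on ", nrow(x$data),
      " observations; ", if (x$converged) "converged" else "NOT converged",
      "\n", sep = "")
  invisible(x)
}

#' @rdname fit_flow_model
#' @export
summary.flow_fit <- function(object, ...) {
  print(object)
  cat("residual sd: ", format(stats::sd(residuals(object)), digits = 4),
      "\n", sep = "")
  invisible(object)
}
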
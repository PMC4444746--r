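#' Local normalized sensitivity coefficient of a scalar model output
#'
#' Forward finite-difference sensitivity: the named parameter is perturbed
#' by a relative `step` (default 1%) with every other parameter held fixed,
#' and the normalized coefficient
#' \deqn{SC = \frac{(f(p(1+h)) - f(p)) / f(p)}{h}}
#' is returned — the fractional output change per fractional parameter
#' change. `|SC| > 0.5` is the conventional threshold for a highly sensitive
#' parameter. A central difference (more accurate, one extra evaluation) is
#' available via `method = "central"`.
#'
#' Parameters whose baseline value is exactly zero cannot be perturbed
#' relatively; they are perturbed by an absolute `zero_step` with a warning,
#' and SC is the output change per absolute step (interpret with care).
#'
#' @param f A function taking a named list (or vector) of parameters and
#'   returning a scalar.
#' @param params Named list/vector of baseline parameter values.
#' @param name Name of the parameter to perturb.
#' @param step Relative perturbation, default 0.01 (1%).
#' @param method `"forward"` (default) or `"central"`.
#' @param zero_step Absolute perturbation used when the baseline value is 0.
#' @return An object of class `"sensitivity_result"`: `parameter`, `sc`,
#'   `perturbation`, `baseline_output`, `baseline_value`, `method`.
#' @examples
#' normalized_sc(function(p) p$a^2, list(a = 3), "a")  # 2.01 at 1% step
#' @export
normalized_sc <- function(f, params, name, step = 0.01,
                          method = c("forward", "central"),
                          zero_step = 1e-6) {
  method <- match.arg(method)
  stopifnot(is.function(f), step > 0)
  params <- as.list(params)
  if (!name %in% names(params)) {
    stop("parameter '", name, "' not found in params", call. = FALSE)
  }
  p0 <- params[[name]]
  f0 <- f(params)
  if (!is.finite(f0)) {
    stop("model output non-finite at baseline (parameter '", name, "')",
         call. = FALSE)
  }
  if (f0 == 0) {
    stop("baseline model output is zero for parameter '", name,
         "': normalized sensitivity undefined", call. = FALSE)
  }
  eval_at <- function(value) {
    p <- params
    p[[name]] <- value
    out <- f(p)
    if (!is.finite(out)) {
      stop("model output non-finite when perturbing '", name, "' to ",
           format(value), call. = FALSE)
    }
    out
  }
  if (p0 == 0) {
    warning("parameter '", name, "' is zero at baseline; using absolute ",
            "perturbation ", zero_step, call. = FALSE)
    delta <- zero_step
    sc <- switch(method,
      forward = (eval_at(delta) - f0) / f0 / delta,
      central = (eval_at(delta) - eval_at(-delta)) / f0 / (2 * delta))
  } else {
    sc <- switch(method,
      forward = (eval_at(p0 * (1 + step)) - f0) / f0 / step,
      central = (eval_at(p0 * (1 + step)) - eval_at(p0 * (1 - step))) /
        f0 / (2 * step))
  }
  structure(
    list(parameter = name, sc = sc, perturbation = step,
         baseline_output = f0, baseline_value = p0, method = method),
    class = "sensitivity_result"
  )
}

#' @rdname normalized_sc
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> d log(output) / d log(", x$parameter, ")\n",
      "  SC ", format(x$sc, digits = 4), "  (", x$method, " difference, ",
      x$perturbation * 100, "% step; baseline output ",
      format(x$baseline_output, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Parameter sensitivity table for the saliva:blood partition coefficient
#'
#' Computes normalized sensitivity coefficients of the partition coefficient
#' with respect to the four chemistry parameters — fraction unbound in
#' plasma, logKow of the non-ionized species, logKow of the ionized species,
#' and pKa — for each supplied species physiology.
#'
#' The ionized-species logKow is defined through `alpha`
#' (`logKow_ionized = logKow_neutral + log10(alpha)`), so perturbing it
#' re-derives `alpha` with the neutral logKow held fixed. Perturbing the
#' non-ionized logKow holds `alpha` fixed (sliding both species' lipophilicity
#' together), so with lipid-free plasma and saliva its SC is exactly 0 —
#' lipophilicity only enters through the ionization permeation penalty and
#' any lipid binding terms. pKa is perturbed multiplicatively like every
#' other parameter (1% of its value in pH units), so the SC magnitude
#' depends on the pKa scale. For a neutral compound the pKa and
#' ionized-logKow rows are reported as `NA` (not applicable).
#'
#' @param compound A [compound()].
#' @param physiologies A list of [species_physiology()] objects.
#' @param step Relative perturbation, default 0.01.
#' @param method `"forward"` or `"central"`, passed to [normalized_sc()].
#' @param ... Passed to [saliva_blood_partition()].
#' @return A data frame with columns `species`, `parameter`, `sc`,
#'   `baseline_p`, `perturbation`.
#' @export
sensitivity_table <- function(compound, physiologies, step = 0.01,
                              method = "forward", ...) {
  stopifnot(inherits(compound, "compound"), is.list(physiologies))
  if (inherits(physiologies, "species_physiology")) {
    physiologies <- list(physiologies)
  }
  # the argument shadows the constructor; recover it by mode
  make_compound <- get("compound", mode = "function")
  ionizable <- compound$ion_class != "neutral"
  base_params <- list(
    fraction_unbound = compound$fraction_unbound_plasma,
    logKow_neutral = compound$logKow_neutral,
    logKow_ionized = logkow_ionized(compound),
    pKa = if (ionizable) compound$pKa else NA_real_)

  rows <- lapply(physiologies, function(phys) {
    stopifnot(inherits(phys, "species_physiology"))
    pfun <- function(p) {
      cmp <- make_compound(compound$name, compound$ion_class,
                      pKa = if (ionizable) p$pKa else NULL,
                      logKow_neutral = p$logKow_neutral,
                      # alpha follows the ionized-species lipophilicity;
                      # neutral-species perturbations keep alpha fixed
                      alpha = if (ionizable)
                        10^(p$logKow_ionized - base_params$logKow_neutral)
                      else 1,
                      fraction_unbound_plasma = p$fraction_unbound)
      saliva_blood_partition(cmp, phys, ...)$p_sal_bl
    }
    baseline <- pfun(base_params)
    one <- function(nm) {
      if (!ionizable && nm %in% c("pKa", "logKow_ionized")) {
        return(NA_real_)
      }
      normalized_sc(pfun, base_params, nm, step = step, method = method)$sc
    }
    data.frame(
      species = phys$name,
      parameter = names(base_params),
      sc = vapply(names(base_params), one, numeric(1)),
      baseline_p = baseline,
      perturbation = step,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
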
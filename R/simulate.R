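#' Coupled blood/saliva pharmacokinetic model
#'
#' A one-compartment parent -> metabolite blood driver coupled to a
#' quasi-equilibrium saliva compartment. After an IV bolus at t = 0 the
#' parent is lost to first-order metabolism (mole-for-mole to the
#' metabolite), first-order systemic elimination, and salivary clearance;
#' the metabolite accumulates and is cleared the same two ways. Saliva
#' concentration is slaved to blood through the partition coefficient
#' (`C_sal = P * C_bl`) and the salivary mass-elimination rate is
#' `Q_sal(t) * C_sal` (passive mode) or a saturable Michaelis-Menten flux
#' of the free blood concentration (`transport_mode = "michaelis_menten"`).
#'
#' @param parent,metabolite [compound()] records. `metabolite = NULL` gives
#'   a single-analyte model.
#' @param volume Distribution volume(s), L: either one value for both
#'   analytes or a named-free vector `c(parent, metabolite)`.
#' @param k_met First-order parent -> metabolite rate, 1/h.
#' @param k_elim Systemic elimination rate(s), 1/h, one value or
#'   `c(parent, metabolite)`.
#' @param partition Saliva:blood partition coefficient(s), one value or
#'   `c(parent, metabolite)` — from [saliva_blood_partition()] or measured.
#' @param flow A [flow_model()] for salivary flow (mL/h).
#' @param transport_mode `"passive"` (default) or `"michaelis_menten"`.
#' @param Tmax,Km Michaelis-Menten constants (umol/h and uM); required
#'   positive in MM mode.
#' @param dose IV bolus dose, umol.
#' @param body_weight Body weight, kg (bookkeeping only).
#' @return An object of class `"saliva_pk_model"`.
#' @examples
#' tcpy <- compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
#'                  alpha = 0.013, fraction_unbound_plasma = 0.015)
#' m <- saliva_pk_model(parent = tcpy, volume = 0.2, k_met = 0,
#'                      k_elim = 0.5, partition = 0.058,
#'                      flow = flow_model(2, 0.5, 1), dose = 1)
#' tc <- simulate(m, t_end = 2)
#' head(tc)
#' @export
saliva_pk_model <- function(parent, metabolite = NULL, volume,
                            k_met = 0, k_elim = 0, partition,
                            flow = flow_model(0, 0, 0),
                            transport_mode = c("passive", "michaelis_menten"),
                            Tmax = NA_real_, Km = NA_real_,
                            dose, body_weight = NA_real_) {
  transport_mode <- match.arg(transport_mode)
  stopifnot(inherits(parent, "compound"), inherits(flow, "flow_model"))
  if (!is.null(metabolite)) stopifnot(inherits(metabolite, "compound"))
  n <- if (is.null(metabolite)) 1L else 2L
  volume <- rep_len(as.numeric(volume), n)
  k_elim <- rep_len(as.numeric(k_elim), n)
  partition <- rep_len(as.numeric(partition), n)
  if (any(volume <= 0)) stop("volumes must be positive", call. = FALSE)
  if (any(c(k_met, k_elim) < 0)) stop("rates must be nonnegative",
                                      call. = FALSE)
  if (any(partition < 0)) stop("partition coefficients must be nonnegative",
                               call. = FALSE)
  if (!is.finite(dose) || dose < 0) stop("dose must be nonnegative",
                                         call. = FALSE)
  if (is.null(metabolite) && k_met > 0) {
    stop("k_met > 0 requires a metabolite record", call. = FALSE)
  }
  if (transport_mode == "michaelis_menten" &&
      (!is.finite(Tmax) || Tmax <= 0 || !is.finite(Km) || Km <= 0)) {
    stop("michaelis_menten mode requires Tmax > 0 and Km > 0", call. = FALSE)
  }
  structure(
    list(parent = parent, metabolite = metabolite, volume = volume,
         k_met = as.numeric(k_met), k_elim = k_elim, partition = partition,
         flow = flow, transport_mode = transport_mode,
         Tmax = as.numeric(Tmax), Km = as.numeric(Km),
         dose = as.numeric(dose), body_weight = as.numeric(body_weight)),
    class = "saliva_pk_model"
  )
}

#' @rdname saliva_pk_model
#' @param x A `saliva_pk_model`.
#' @param ... Unused.
#' @export
print.saliva_pk_model <- function(x, ...) {
  analytes <- c(x$parent$name, if (!is.null(x$metabolite)) x$metabolite$name)
  cat("<saliva_pk_model> ", paste(analytes, collapse = " -> "),
      "  (", x$transport_mode, " salivary transport)\n", sep = "")
  cat("  dose ", x$dose, " umol IV bolus; V ",
      paste(x$volume, collapse = "/"), " L; k_met ", x$k_met,
      " 1/h; k_elim ", paste(x$k_elim, collapse = "/"), " 1/h; P ",
      paste(x$partition, collapse = "/"), "\n", sep = "")
  print(x$flow)
  invisible(x)
}

#' Simulate the blood/saliva time course
#'
#' Integrates the model of [saliva_pk_model()] with a stiff-capable adaptive
#' solver (relative tolerance 1e-8, absolute 1e-12) and reports
#' concentrations on a fixed output grid. Mass balance closes at every
#' output time: blood amounts + cumulative systemic elimination + cumulative
#' saliva elimination = dose.
#'
#' @param object A [saliva_pk_model()].
#' @param nsim,seed Unused (the model is deterministic); kept for
#'   compatibility with [stats::simulate()].
#' @param t_end End of the simulation window, h.
#' @param n_grid Number of output time points (evenly spaced from 0).
#' @param ... Unused.
#' @return A data frame of class `"saliva_timecourse"`, one row per time x
#'   analyte: `time` (h), `analyte`, `blood_conc` (uM), `free_conc` (uM),
#'   `saliva_conc` (uM), `cum_saliva_amount` (umol), `cum_eliminated`
#'   (umol), `flow_rate` (mL/h).
#' @export
simulate.saliva_pk_model <- function(object, nsim = 1, seed = NULL,
                                     t_end = 2, n_grid = 201L, ...) {
  stopifnot(t_end > 0, n_grid >= 2L)
  m <- object
  two <- !is.null(m$metabolite)
  times <- seq(0, t_end, length.out = n_grid)

  sal_rate <- function(t, amount, i) {
    conc <- amount / m$volume[i]               # uM = umol / L
    if (m$transport_mode == "passive") {
      # Q mL/h * C umol/L -> umol/h (mL -> L)
      flow_rate(t, m$flow) / 1000 * saliva_concentration(conc, m$partition[i])
    } else {
      cmp <- if (i == 1L) m$parent else m$metabolite
      michaelis_menten_rate(free_concentration(conc, cmp), m$Tmax, m$Km)
    }
  }

  deriv <- function(t, y, parms) {
    sal_p <- sal_rate(t, y[["Ap"]], 1L)
    dAp <- -(m$k_met + m$k_elim[1]) * y[["Ap"]] - sal_p
    dEp <- m$k_elim[1] * y[["Ap"]]
    if (two) {
      sal_m <- sal_rate(t, y[["Am"]], 2L)
      dAm <- m$k_met * y[["Ap"]] - m$k_elim[2] * y[["Am"]] - sal_m
      dEm <- m$k_elim[2] * y[["Am"]]
      list(c(dAp, dAm, dEp, dEm, sal_p, sal_m))
    } else {
      list(c(dAp, dEp, sal_p))
    }
  }

  y0 <- if (two) c(Ap = m$dose, Am = 0, Ep = 0, Em = 0, Sp = 0, Sm = 0)
        else c(Ap = m$dose, Ep = 0, Sp = 0)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed (lsoda istate ", attr(sol, "istate")[1],
         "); inspect model rates and flow for singularities", call. = FALSE)
  }
  sol <- as.data.frame(sol)
  state_cols <- setdiff(names(sol), "time")
  neg <- vapply(sol[state_cols], function(v) any(v < 0), logical(1))
  if (any(neg)) {
    worst <- min(vapply(sol[state_cols], min, numeric(1)))
    if (worst < -1e-12) {
      warning("negative state values down to ", format(worst),
              " clipped to 0", call. = FALSE)
    }
    sol[state_cols] <- lapply(sol[state_cols], pmax, 0)
  }

  build <- function(i, amount, cum_sal, cum_elim) {
    cmp <- if (i == 1L) m$parent else m$metabolite
    conc <- amount / m$volume[i]
    data.frame(
      time = sol$time, analyte = cmp$name, blood_conc = conc,
      free_conc = free_concentration(conc, cmp),
      saliva_conc = saliva_concentration(conc, m$partition[i]),
      cum_saliva_amount = cum_sal, cum_eliminated = cum_elim,
      flow_rate = flow_rate(sol$time, m$flow),
      stringsAsFactors = FALSE)
  }
  tc <- build(1L, sol$Ap, sol$Sp, sol$Ep)
  if (two) tc <- rbind(tc, build(2L, sol$Am, sol$Sm, sol$Em))
  attr(tc, "model") <- m
  attr(tc, "mass_balance") <-
    if (two) (sol$Ap + sol$Am + sol$Ep + sol$Em + sol$Sp + sol$Sm) / max(m$dose, .Machine$double.eps)
    else (sol$Ap + sol$Ep + sol$Sp) / max(m$dose, .Machine$double.eps)
  class(tc) <- c("saliva_timecourse", "data.frame")
  tc
}

#' @rdname simulate.saliva_pk_model
#' @param x A `saliva_timecourse`.
#' @export
print.saliva_timecourse <- function(x, ...) {
  m <- attr(x, "model")
  cat("<saliva_timecourse> ", length(unique(x$analyte)), " analyte(s), ",
      length(unique(x$time)), " time points over ",
      format(max(x$time)), " h\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' @rdname simulate.saliva_pk_model
#' @export
plot.saliva_timecourse <- function(x, ...) {
  an <- unique(x$analyte)
  op <- graphics::par(mfrow = c(1, length(an)))
  on.exit(graphics::par(op))
  for (a in an) {
    d <- x[x$analyte == a, ]
    graphics::matplot(d$time, cbind(d$blood_conc, d$saliva_conc),
                      type = "l", lty = 1:2, col = c("black", "blue"),
                      xlab = "time (h)", ylab = "concentration (uM)",
                      main = a, ...)
    graphics::legend("topright", c("blood", "saliva"), lty = 1:2,
                     col = c("black", "blue"), bty = "n")
  }
  invisible(x)
}

#' Trapezoidal AUC of one analyte's blood or saliva curve
#'
#' @param timecourse A `saliva_timecourse`.
#' @param analyte Analyte name (defaults to the first).
#' @param what `"blood_conc"`, `"saliva_conc"` or `"free_conc"`.
#' @return AUC, uM * h.
#' @export
timecourse_auc <- function(timecourse, analyte = NULL,
                           what = c("blood_conc", "saliva_conc",
                                    "free_conc")) {
  what <- match.arg(what)
  stopifnot(inherits(timecourse, "saliva_timecourse"))
  if (is.null(analyte)) analyte <- timecourse$analyte[1]
  d <- timecourse[timecourse$analyte == analyte, ]
  if (nrow(d) == 0) stop("unknown analyte '", analyte, "'", call. = FALSE)
  y <- d[[what]]
  sum(diff(d$time) * (y[-1] + y[-length(y)]) / 2)
}
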
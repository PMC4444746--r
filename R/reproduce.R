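#' Write partition results as tidy CSV and a JSON sidecar
#'
#' One row per compound x species with the partition coefficient, unbound
#' fractions and trapping ratio; the JSON sidecar carries the full
#' diagnostics for provenance.
#'
#' @param results A list of `partition_result` objects (see
#'   [saliva_blood_partition()]).
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON sidecar path (default: CSV path with a
#'   `.json` extension).
#' @param reciprocal Logical; also emit the blood:saliva (reciprocal)
#'   orientation column for comparison with plasma:saliva reports.
#' @return Invisibly, the data frame written.
#' @export
write_partition_results <- function(results, csv_path, json_path = NULL,
                                    reciprocal = FALSE) {
  if (inherits(results, "partition_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  if (reciprocal) df$p_bl_sal <- 1 / df$p_sal_bl
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (is.null(json_path)) {
    json_path <- sub("\\.csv$", ".json", csv_path)
  }
  jsonlite::write_json(lapply(results, function(r) r[c(
    "p_sal_bl", "f_u_plasma", "f_u_saliva", "trapping_ratio",
    "diagnostics")]), json_path, auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Write a simulated time course as tidy CSV (and JSON)
#'
#' @param timecourse A `saliva_timecourse` from
#'   [simulate.saliva_pk_model()].
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON path; skipped when `NULL`.
#' @return Invisibly, the path written.
#' @export
write_timecourse <- function(timecourse, csv_path, json_path = NULL) {
  stopifnot(inherits(timecourse, "saliva_timecourse"))
  utils::write.csv(as.data.frame(timecourse), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(timecourse), json_path,
                         dataframe = "rows", digits = NA)
  }
  invisible(csv_path)
}

#' Recompute the worked partitioning artifacts
#'
#' Regenerates, from the built-in scenario library, the package's worked
#' results as CSV files in `out_dir`:
#' \describe{
#'   \item{`table1_alpha`}{TCPy's ionized:neutral affinity ratio derived
#'     from its two-pH lipophilicity entries (logKow 3.2 at pH 3, 1.3 at
#'     pH 7).}
#'   \item{`table3`}{Normalized sensitivity coefficients of the generic
#'     compound's partition coefficient (fraction unbound, both logKow
#'     values, pKa) for human and rat.}
#'   \item{`fig4`}{Partition coefficients across plasma binding levels
#'     (fraction unbound 0.1/0.5/0.9, pKa 7) for both species, with the
#'     human:rat ratio.}
#'   \item{`fig5`}{Partition coefficients across pKa 4/7/10 at 50%
#'     binding for both species, with the human:rat ratio.}
#'   \item{`tcpy_rat_partition`}{The adapted-Schmitt TCPy prediction under
#'     measured rat physiology (plasma pH 7.8, saliva pH 8.9).}
#' }
#' Each CSV gets a JSON sidecar recording the package version, seed and
#' target. With `plot = TRUE`, `fig4`/`fig5` additionally write a PDF of
#' the species comparison (a convenience; the CSV is the data of record).
#'
#' @param target One of `"table1_alpha"`, `"table3"`, `"fig4"`, `"fig5"`,
#'   `"tcpy_rat_partition"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in provenance (the computations are
#'   deterministic).
#' @param plot Also write a PDF for the figure targets.
#' @return Invisibly, the data frame written.
#' @export
reproduce <- function(target = c("table1_alpha", "table3", "fig4", "fig5",
                                 "tcpy_rat_partition"),
                      out_dir = ".", seed = 20150527, plot = FALSE) {
  target <- match.arg(target)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lib <- builtin_library(seed = seed)
  rat_gen <- lib$species$rat
  human <- lib$species$human
  path <- file.path(out_dir, paste0(target, ".csv"))

  df <- switch(target,
    table1_alpha = {
      data.frame(compound = "TCPy", logKow_pH3 = 3.2, logKow_pH7 = 1.3,
                 alpha = round(derive_alpha(3.2, 1.3), 3))
    },
    table3 = {
      sensitivity_table(generic_compound(0.5, 7), list(human, rat_gen))
    },
    fig4 = {
      fu <- c(0.1, 0.5, 0.9)
      ph <- vapply(fu, function(f)
        saliva_blood_partition(generic_compound(f, 7), human)$p_sal_bl,
        numeric(1))
      pr <- vapply(fu, function(f)
        saliva_blood_partition(generic_compound(f, 7), rat_gen)$p_sal_bl,
        numeric(1))
      data.frame(fraction_unbound = fu, p_sal_bl_human = ph,
                 p_sal_bl_rat = pr, human_to_rat_ratio = ph / pr)
    },
    fig5 = {
      pka <- c(4, 7, 10)
      ph <- vapply(pka, function(k)
        saliva_blood_partition(generic_compound(0.5, k), human)$p_sal_bl,
        numeric(1))
      pr <- vapply(pka, function(k)
        saliva_blood_partition(generic_compound(0.5, k), rat_gen)$p_sal_bl,
        numeric(1))
      data.frame(pKa = pka, p_sal_bl_human = ph, p_sal_bl_rat = pr,
                 human_to_rat_ratio = ph / pr)
    },
    tcpy_rat_partition = {
      as.data.frame(
        saliva_blood_partition(tcpy_compound(), lib$species$rat_tcpy))
    })

  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(target = target, seed = seed,
         package = as.character(utils::packageVersion("salivapk")),
         created = format(Sys.time(), tz = "UTC"),
         columns = names(df)),
    sub("\\.csv$", "_provenance.json", path), auto_unbox = TRUE)

  if (plot && target %in% c("fig4", "fig5")) {
    xcol <- if (target == "fig4") "fraction_unbound" else "pKa"
    pdf_path <- file.path(out_dir, paste0(target, ".pdf"))
    grDevices::pdf(pdf_path, width = 5, height = 4)
    graphics::matplot(df[[xcol]], cbind(df$p_sal_bl_human, df$p_sal_bl_rat),
                      type = "b", pch = 16, lty = 1,
                      col = c("firebrick", "steelblue"),
                      xlab = xcol, ylab = "P_sal:bl", log = "y")
    graphics::legend("topleft", c("human", "rat"), pch = 16,
                     col = c("firebrick", "steelblue"), bty = "n")
    grDevices::dev.off()
  }
  invisible(df)
}
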
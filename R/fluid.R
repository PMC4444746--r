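#' Define a biological fluid / compartment composition
#'
#' A `fluid` records the composition of a body fluid or tissue space as
#' volume fractions — protein, water, neutral lipid, cells — plus its pH.
#' Plasma and (mixed) saliva are the two fluids the partition algorithm
#' works with; the interstitial fraction defaults to the complement of the
#' cellular fraction.
#'
#' @param name Fluid label.
#' @param pH pH of the fluid, in \[0, 14\].
#' @param fraction_water Water volume fraction.
#' @param fraction_protein Protein volume fraction.
#' @param fraction_lipid Neutral-lipid volume fraction. Plasma and saliva
#'   carry no tabulated lipid; the term exists structurally and defaults
#'   to 0.
#' @param fraction_cells Cellular volume fraction (0 for cell-free saliva).
#' @param fraction_interstitial Interstitial volume fraction; defaults to
#'   `1 - fraction_cells` and must equal it.
#' @return An object of class `"fluid"`.
#' @examples
#' rat_plasma <- fluid("rat plasma", pH = 7.8,
#'                     fraction_water = 0.915, fraction_protein = 0.073)
#' rat_saliva <- fluid("rat saliva", pH = 8.9,
#'                     fraction_water = 0.98, fraction_protein = 0.003)
#' @export
fluid <- function(name, pH, fraction_water, fraction_protein,
                  fraction_lipid = 0, fraction_cells = 0,
                  fraction_interstitial = 1 - fraction_cells) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_pH(pH)
  fr <- c(fraction_water = fraction_water, fraction_protein = fraction_protein,
          fraction_lipid = fraction_lipid, fraction_cells = fraction_cells,
          fraction_interstitial = fraction_interstitial)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("all volume fractions must lie in [0, 1]", call. = FALSE)
  }
  if (fraction_water + fraction_protein > 1 + 1e-12) {
    stop("fraction_water + fraction_protein exceeds 1", call. = FALSE)
  }
  if (abs(fraction_interstitial + fraction_cells - 1) > 1e-9) {
    stop("fraction_interstitial + fraction_cells must equal 1", call. = FALSE)
  }
  structure(
    list(name = name, pH = as.numeric(pH),
         fraction_water = as.numeric(fraction_water),
         fraction_protein = as.numeric(fraction_protein),
         fraction_lipid = as.numeric(fraction_lipid),
         fraction_cells = as.numeric(fraction_cells),
         fraction_interstitial = as.numeric(fraction_interstitial)),
    class = "fluid"
  )
}

#' @rdname fluid
#' @param x A `fluid`.
#' @param ... Unused.
#' @export
print.fluid <- function(x, ...) {
  cat("<fluid> ", x$name, "  pH ", format(x$pH), "\n",
      "  water ", format(x$fraction_water),
      " | protein ", format(x$fraction_protein),
      " | lipid ", format(x$fraction_lipid),
      " | cells ", format(x$fraction_cells), "\n", sep = "")
  invisible(x)
}

#' Species physiology: plasma, saliva, body weight and salivary flow
#'
#' Bundles everything the partition and kinetics layers need to know about
#' one species: its plasma and saliva compositions (as [fluid()] objects),
#' body weight, and a salivary [flow_model()].
#'
#' @param name Species label (e.g. `"rat"`, `"human"`).
#' @param plasma,saliva [fluid()] objects.
#' @param body_weight Body weight, kg.
#' @param flow A [flow_model()] describing salivary flow, or `NULL`.
#' @return An object of class `"species_physiology"`.
#' @export
species_physiology <- function(name, plasma, saliva, body_weight = NA_real_,
                               flow = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(plasma, "fluid"), inherits(saliva, "fluid"))
  if (!is.na(body_weight) && body_weight <= 0) {
    stop("body_weight must be positive", call. = FALSE)
  }
  if (!is.null(flow)) stopifnot(inherits(flow, "flow_model"))
  structure(list(name = name, plasma = plasma, saliva = saliva,
                 body_weight = as.numeric(body_weight), flow = flow),
            class = "species_physiology")
}

#' @rdname species_physiology
#' @param x A `species_physiology`.
#' @param ... Unused.
#' @export
print.species_physiology <- function(x, ...) {
  cat("<species_physiology> ", x$name,
      if (!is.na(x$body_weight)) paste0("  (", x$body_weight, " kg)"),
      "\n", sep = "")
  cat("  plasma pH ", format(x$plasma$pH), ", saliva pH ",
      format(x$saliva$pH), "\n", sep = "")
  invisible(x)
}
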
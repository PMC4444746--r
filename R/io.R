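#' @keywords internal
.assert_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown key(s) in ", where, ": ",
         paste(sQuote(unknown), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

.compound_from_config <- function(cfg, where = "compound") {
  .assert_known_keys(cfg, c("name", "ion_class", "pKa", "logKow_neutral",
                            "logKow_ionized", "alpha",
                            "fraction_unbound_plasma"), where)
  for (k in c("name", "ion_class")) {
    if (is.null(cfg[[k]])) stop(where, ": missing key '", k, "'",
                                call. = FALSE)
  }
  alpha <- cfg$alpha
  if (is.null(alpha) && !is.null(cfg$logKow_ionized)) {
    alpha <- derive_alpha(cfg$logKow_neutral, cfg$logKow_ionized)
  }
  compound(name = cfg$name, ion_class = cfg$ion_class, pKa = cfg$pKa,
           logKow_neutral = if (is.null(cfg$logKow_neutral)) 0
                            else cfg$logKow_neutral,
           alpha = if (is.null(alpha)) 1 else alpha,
           fraction_unbound_plasma =
             if (is.null(cfg$fraction_unbound_plasma)) 1
             else cfg$fraction_unbound_plasma)
}

.fluid_from_config <- function(cfg, name, where) {
  .assert_known_keys(cfg, c("pH", "fraction_water", "fraction_protein",
                            "fraction_lipid", "fraction_cells",
                            "fraction_interstitial"), where)
  for (k in c("pH", "fraction_water", "fraction_protein")) {
    if (is.null(cfg[[k]])) stop(where, ": missing key '", k, "'",
                                call. = FALSE)
  }
  args <- c(list(name = name), cfg)
  do.call(fluid, args)
}

.species_from_config <- function(cfg, where = "species") {
  .assert_known_keys(cfg, c("name", "body_weight", "plasma", "saliva",
                            "flow"), where)
  for (k in c("name", "plasma", "saliva")) {
    if (is.null(cfg[[k]])) stop(where, ": missing key '", k, "'",
                                call. = FALSE)
  }
  fl <- NULL
  if (!is.null(cfg$flow)) {
    .assert_known_keys(cfg$flow, c("A", "B", "C"),
                       paste0(where, "$flow"))
    fl <- flow_model(cfg$flow$A, cfg$flow$B, cfg$flow$C)
  }
  species_physiology(
    name = cfg$name,
    plasma = .fluid_from_config(cfg$plasma, paste(cfg$name, "plasma"),
                                paste0(where, "$plasma")),
    saliva = .fluid_from_config(cfg$saliva, paste(cfg$name, "saliva"),
                                paste0(where, "$saliva")),
    body_weight = if (is.null(cfg$body_weight)) NA_real_
                  else cfg$body_weight,
    flow = fl)
}

.simulation_keys <- c("name", "parent", "metabolite", "species", "volume",
                      "k_met", "k_elim", "partition", "transport_mode",
                      "Tmax", "Km", "dose", "t_end")

#' Load a scenario bundle from a YAML config file
#'
#' A scenario bundle collects compounds, species physiologies and
#' simulation definitions in one structured YAML document. The schema is
#' strict: unknown keys are rejected with an itemized diagnostic rather than
#' ignored, because a silently misspelled `pKa` or `pH` would corrupt the
#' science quietly. Cross-references (a simulation's `parent`/`species`)
#' must resolve within the bundle.
#'
#' @param path Path to a YAML file.
#' @return An object of class `"scenario_bundle"`: named lists `compounds`
#'   (of [compound()]), `species` (of [species_physiology()]),
#'   `simulations` (validated raw configs; instantiate with
#'   [build_simulation()]), and `outputs`.
#' @examples
#' path <- system.file("extdata", "tcpy_rat.yaml", package = "salivapk")
#' bundle <- load_bundle(path)
#' bundle$compounds$TCPy
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || length(cfg) == 0) {
    stop("config file is empty: ", path, call. = FALSE)
  }
  bundle_from_config(cfg)
}

#' @rdname load_bundle
#' @param cfg A list with the bundle structure (as parsed from YAML).
#' @export
bundle_from_config <- function(cfg) {
  .assert_known_keys(cfg, c("compounds", "species", "simulations",
                            "outputs"), "bundle")
  compounds <- lapply(seq_along(cfg$compounds), function(i) {
    .compound_from_config(cfg$compounds[[i]], paste0("compounds[", i, "]"))
  })
  names(compounds) <- vapply(compounds, `[[`, character(1), "name")
  if (anyDuplicated(names(compounds))) {
    stop("duplicate compound names in bundle", call. = FALSE)
  }
  species <- lapply(seq_along(cfg$species), function(i) {
    .species_from_config(cfg$species[[i]], paste0("species[", i, "]"))
  })
  names(species) <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(names(species))) {
    stop("duplicate species names in bundle", call. = FALSE)
  }
  simulations <- cfg$simulations
  for (i in seq_along(simulations)) {
    sim <- simulations[[i]]
    .assert_known_keys(sim, .simulation_keys,
                       paste0("simulations[", i, "]"))
    for (ref in c("parent", "metabolite")) {
      if (!is.null(sim[[ref]]) && !sim[[ref]] %in% names(compounds)) {
        stop("simulations[", i, "]: ", ref, " '", sim[[ref]],
             "' not found among bundle compounds", call. = FALSE)
      }
    }
    if (!is.null(sim$species) && !sim$species %in% names(species)) {
      stop("simulations[", i, "]: species '", sim$species,
           "' not found among bundle species", call. = FALSE)
    }
  }
  structure(list(compounds = compounds, species = species,
                 simulations = simulations,
                 outputs = cfg$outputs),
            class = "scenario_bundle")
}

#' @rdname load_bundle
#' @param bundle A `scenario_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  cmp_cfg <- lapply(unname(bundle$compounds), function(cmp) {
    out <- list(name = cmp$name, ion_class = cmp$ion_class)
    if (!is.null(cmp$pKa)) out$pKa <- cmp$pKa
    out$logKow_neutral <- cmp$logKow_neutral
    out$alpha <- cmp$alpha
    out$fraction_unbound_plasma <- cmp$fraction_unbound_plasma
    out
  })
  fl_cfg <- function(fl) {
    list(pH = fl$pH, fraction_water = fl$fraction_water,
         fraction_protein = fl$fraction_protein,
         fraction_lipid = fl$fraction_lipid,
         fraction_cells = fl$fraction_cells)
  }
  sp_cfg <- lapply(unname(bundle$species), function(sp) {
    out <- list(name = sp$name)
    if (!is.na(sp$body_weight)) out$body_weight <- sp$body_weight
    out$plasma <- fl_cfg(sp$plasma)
    out$saliva <- fl_cfg(sp$saliva)
    if (!is.null(sp$flow)) {
      out$flow <- list(A = sp$flow$A, B = sp$flow$B, C = sp$flow$C)
    }
    out
  })
  cfg <- list(compounds = cmp_cfg, species = sp_cfg)
  if (!is.null(bundle$simulations)) cfg$simulations <- bundle$simulations
  if (!is.null(bundle$outputs)) cfg$outputs <- bundle$outputs
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname load_bundle
#' @param x A `scenario_bundle`.
#' @param ... Unused.
#' @export
print.scenario_bundle <- function(x, ...) {
  cat("<scenario_bundle> ", length(x$compounds), " compound(s), ",
      length(x$species), " species, ", length(x$simulations),
      " simulation(s)\n", sep = "")
  cat("  compounds: ", paste(names(x$compounds), collapse = ", "), "\n",
      "  species:   ", paste(names(x$species), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Instantiate a simulation definition from a bundle
#'
#' Resolves a simulation config's cross-references against the bundle's
#' compounds and species and returns a ready-to-run [saliva_pk_model()].
#' A `partition` entry of `"computed"` (the default) derives the partition
#' coefficient(s) from the adapted Schmitt algorithm for the referenced
#' species; a numeric entry is used as measured.
#'
#' @param bundle A [load_bundle()] result.
#' @param which Simulation index or name.
#' @return A list: `model` (a [saliva_pk_model()]) and `t_end`.
#' @export
build_simulation <- function(bundle, which = 1L) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  sims <- bundle$simulations
  if (length(sims) == 0) stop("bundle has no simulations", call. = FALSE)
  if (is.character(which)) {
    idx <- match(which, vapply(sims, function(s) s$name %||% "",
                               character(1)))
    if (is.na(idx)) stop("no simulation named '", which, "'", call. = FALSE)
  } else idx <- as.integer(which)
  sim <- sims[[idx]]
  parent <- bundle$compounds[[sim$parent]]
  metabolite <- if (!is.null(sim$metabolite))
    bundle$compounds[[sim$metabolite]] else NULL
  phys <- bundle$species[[sim$species]]
  n <- if (is.null(metabolite)) 1L else 2L
  part <- sim$partition %||% "computed"
  if (identical(part, "computed")) {
    cmps <- c(list(parent), if (n == 2L) list(metabolite))
    part <- vapply(cmps, function(cmp) {
      saliva_blood_partition(cmp, phys)$p_sal_bl
    }, numeric(1))
  }
  model <- saliva_pk_model(
    parent = parent, metabolite = metabolite,
    volume = unlist(sim$volume), k_met = sim$k_met %||% 0,
    k_elim = unlist(sim$k_elim %||% 0), partition = as.numeric(part),
    flow = if (!is.null(phys$flow)) phys$flow else flow_model(0, 0, 0),
    transport_mode = sim$transport_mode %||% "passive",
    Tmax = sim$Tmax %||% NA_real_, Km = sim$Km %||% NA_real_,
    dose = sim$dose, body_weight = phys$body_weight)
  list(model = model, t_end = sim$t_end %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
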
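# run code under a private RNG stream, restoring the caller's seed
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default physiologies and worked compounds
#'
#' `tcpy_compound()` is trichloropyridinol (TCPy), the major chlorpyrifos
#' metabolite: a weak acid, pKa 4.55, logKow 3.2 at pH 3 (neutral-dominant)
#' falling to 1.3 at pH 7, hence `alpha` ~0.013, and 98.5% plasma-protein
#' bound. `generic_compound()` builds one member of the generic monoprotic
#' base family used for cross-species scans: logKow 2 (non-ionized) and -1
#' (ionized), i.e. `alpha` 0.001, with selectable pKa and plasma binding.
#'
#' `rat_physiology()` and `human_physiology()` carry plasma (protein 0.073,
#' water 0.915) and cell-free saliva (protein 0.003, water 0.98).
#' Stimulated rat saliva is alkaline (pH 8.9) while human mixed saliva is
#' slightly acidic (pH 6.7); rat plasma pH defaults to 7.4 for the generic
#' scans but was measured at 7.8 in the anesthetized TCPy experiments —
#' pass `plasma_pH = 7.8` to reproduce those.
#'
#' @param fraction_unbound,pKa Generic-compound knobs.
#' @param plasma_pH,saliva_pH Override fluid pH values.
#' @param body_weight Body weight, kg.
#' @param flow Optional [flow_model()]; the rat default is `NULL` (supply a
#'   fitted pilocarpine flow when simulating).
#' @return A [compound()] or [species_physiology()].
#' @export
tcpy_compound <- function() {
  # tabulated alpha 0.013; derive_alpha(3.2, 1.3) reproduces it at 3 decimals
  compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
           alpha = 0.013, fraction_unbound_plasma = 0.015)
}

#' @rdname tcpy_compound
#' @export
generic_compound <- function(fraction_unbound = 0.5, pKa = 7) {
  compound(sprintf("generic_fu%g_pKa%g", fraction_unbound, pKa),
           "base", pKa = pKa, logKow_neutral = 2,
           alpha = derive_alpha(2, -1),
           fraction_unbound_plasma = fraction_unbound)
}

#' @rdname tcpy_compound
#' @export
rat_physiology <- function(plasma_pH = 7.4, saliva_pH = 8.9,
                           body_weight = 0.25, flow = NULL) {
  species_physiology(
    "rat",
    plasma = fluid("rat plasma", plasma_pH, fraction_water = 0.915,
                   fraction_protein = 0.073),
    saliva = fluid("rat saliva", saliva_pH, fraction_water = 0.98,
                   fraction_protein = 0.003, fraction_cells = 0),
    body_weight = body_weight, flow = flow)
}

#' @rdname tcpy_compound
#' @export
human_physiology <- function(plasma_pH = 7.4, saliva_pH = 6.7,
                             body_weight = 70, flow = NULL) {
  species_physiology(
    "human",
    plasma = fluid("human plasma", plasma_pH, fraction_water = 0.915,
                   fraction_protein = 0.073),
    saliva = fluid("human saliva", saliva_pH, fraction_water = 0.98,
                   fraction_protein = 0.003, fraction_cells = 0),
    body_weight = body_weight, flow = flow)
}

#' Synthetic pilocarpine-stimulated salivary flow measurements
#'
#' Generates a synthetic flow-rate dataset mimicking saliva collection from
#' rats infused with pilocarpine: flows follow `Q(t) = A t^B + C` (default
#' A = 2, B = 0.5, C = 1 mL/h over 4 h) with multiplicative Gaussian noise
#' (default 5% CV). Collection times are log-spaced from `t_min` to
#' `t_max`: a power law with baseline is identified by its early-time
#' behavior, so sampling is densest right after pilocarpine onset — which
#' also matches how flow is measured experimentally (frequent early
#' collections while the stimulated response develops). The generator is
#' deterministic under the given seed and leaves the caller's RNG state
#' untouched.
#'
#' @param n Number of observations.
#' @param flow True [flow_model()] generating the data.
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param t_min,t_max First and last collection times, h.
#' @param seed RNG seed (default 20150527).
#' @return Data frame with `times` (h) and `flows` (mL/h).
#' @export
synthetic_flow_data <- function(n = 40, flow = flow_model(2, 0.5, 1),
                                noise_cv = 0.05, t_min = 0.02, t_max = 4,
                                seed = 20150527) {
  stopifnot(n >= 4, noise_cv >= 0, t_max > t_min, t_min > 0)
  times <- exp(seq(log(t_min), log(t_max), length.out = n))
  .with_seed(seed, {
    flows <- flow_rate(times, flow) * exp(stats::rnorm(n, 0, noise_cv))
    data.frame(times = times, flows = flows)
  })
}

#' Built-in scenario library
#'
#' Ships the worked scenarios as a [scenario_bundle]: TCPy under rat
#' (measured plasma pH 7.8, saliva 8.9) and human (7.4 / 6.7)
#' physiologies, the 3 x 3 generic-compound grid (fraction unbound 0.1,
#' 0.5, 0.9 x pKa 4, 7, 10; monoprotic base, logKow 2 / -1, alpha 0.001)
#' under generic rat and human physiologies (both plasma pH 7.4), and a
#' synthetic pilocarpine flow dataset (attribute `"flow_data"`,
#' regenerated bit-identically under the default seed).
#'
#' @param seed Seed for the synthetic flow fixture.
#' @return A `scenario_bundle` with a `"flow_data"` attribute.
#' @export
builtin_library <- function(seed = 20150527) {
  grid <- expand.grid(fu = c(0.1, 0.5, 0.9), pKa = c(4, 7, 10))
  compounds <- c(
    list(tcpy_compound()),
    lapply(seq_len(nrow(grid)), function(i) {
      generic_compound(grid$fu[i], grid$pKa[i])
    }))
  names(compounds) <- vapply(compounds, `[[`, character(1), "name")
  species <- list(
    rat_tcpy = rat_physiology(plasma_pH = 7.8),
    rat = rat_physiology(),
    human = human_physiology())
  species <- lapply(names(species), function(nm) {
    sp <- species[[nm]]
    sp$name <- nm
    sp
  })
  names(species) <- vapply(species, `[[`, character(1), "name")
  bundle <- structure(
    list(compounds = compounds, species = species,
         simulations = list(), outputs = list()),
    class = "scenario_bundle")
  attr(bundle, "flow_data") <- synthetic_flow_data(seed = seed)
  bundle
}
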
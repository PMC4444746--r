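# shared fixtures built in code
tcpy <- function() {
  compound("TCPy", "acid", pKa = 4.55, logKow_neutral = 3.2,
           alpha = 0.013, fraction_unbound_plasma = 0.015)
}

generic_base <- function(fu = 0.5, pKa = 7) {
  compound("generic", "base", pKa = pKa, logKow_neutral = 2,
           alpha = 0.001, fraction_unbound_plasma = fu)
}

plasma_fluid <- function(pH = 7.4) {
  fluid("plasma", pH, fraction_water = 0.915, fraction_protein = 0.073)
}

saliva_fluid <- function(pH) {
  fluid("saliva", pH, fraction_water = 0.98, fraction_protein = 0.003,
        fraction_cells = 0)
}

phys <- function(plasma_pH, saliva_pH, name = "species") {
  species_physiology(name, plasma = plasma_fluid(plasma_pH),
                     saliva = saliva_fluid(saliva_pH))
}

# Independent brute-force oracle for the saliva:blood partition chain,
# written as a straight transliteration of the closed forms (kept separate
# from the package's compound/fluid machinery on purpose).
oracle_partition <- function(ion_class, pKa, alpha, fu,
                             plasma_pH, saliva_pH,
                             plasma_protein = 0.073,
                             saliva_protein = 0.003) {
  Rat <- function(pH) {
    switch(ion_class,
           acid = 10^(pH - pKa), base = 10^(pKa - pH), neutral = 0)
  }
  if (ion_class == "neutral") alpha <- 1
  beta_p <- (1 - fu) / fu
  beta_s <- beta_p * saliva_protein / plasma_protein
  fu_s <- 1 / (1 + beta_s)
  Rs <- Rat(saliva_pH); Rp <- Rat(plasma_pH)
  trap <- ((1 + Rs) / (1 + alpha * Rs)) / ((1 + Rp) / (1 + alpha * Rp))
  trap * fu / fu_s
}
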
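# TCPy (trichloropyridinol) under measured rat physiology:
# anesthetized, pilocarpine-stimulated animals (plasma pH 7.8, saliva pH 8.9).
compounds:
  - name: TCPy
    ion_class: acid
    pKa: 4.55
    logKow_neutral: 3.2
    alpha: 0.013
    fraction_unbound_plasma: 0.015
species:
  - name: rat
    body_weight: 0.25
    plasma:
      pH: 7.8
      fraction_water: 0.915
      fraction_protein: 0.073
    saliva:
      pH: 8.9
      fraction_water: 0.98
      fraction_protein: 0.003
      fraction_cells: 0
    flow:
      A: 2.0
      B: 0.5
      C: 1.0
simulations:
  - name: tcpy_iv_bolus
    parent: TCPy
    species: rat
    volume: 0.2
    k_met: 0
    k_elim: 0.4
    partition: computed
    dose: 1.0
    t_end: 2.0
    transport_mode: passive
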
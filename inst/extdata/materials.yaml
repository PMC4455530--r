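# Beam-line and target materials.
# density in g/cm^3, composition as element: mass fraction, I_eV is the
# mean excitation energy; when I_eV is omitted it is built from the
# composition by Bragg additivity over the elemental values.
tissue:
  # unit-density water stand-in for soft tissue
  density: 1.0
  composition: {H: 0.111894, O: 0.888106}
  I_eV: 75.0
polyethylene:
  # (CH2)n
  density: 0.97
  composition: {C: 0.8563, H: 0.1437}
water:
  density: 1.0
  composition: {H: 0.111894, O: 0.888106}
  I_eV: 75.0
aluminum:
  density: 2.699
  composition: {Al: 1.0}
  I_eV: 166.0
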
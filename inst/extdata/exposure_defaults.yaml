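# Receptor exposure parameters, standards-derived (HJ 25.3-2019 / USEPA
# dust-exposure conventions), fully overridable. Fuzzy parameters are
# triangular fuzzy numbers [minimum, most-expected, maximum]; the spreads
# (about +/-30% for intake rates, +/-20% for body weight) represent
# plausible receptor variability around the standard default.
# Units: IngR mg/day; InhR m3/day; BW kg; ED yr; EF days/yr; AT days;
# SA cm2; SSAR mg/(cm2 day); ABS unitless; PEF m3/kg.
adult:
  IngR: [70.0, 100.0, 130.0]
  InhR: [10.15, 14.5, 18.85]
  BW: [45.4, 56.8, 68.2]
  ED: 24
  EF: 350
  AT_nc: 8760
  AT_ca: 25550
  SA: 5700
  SSAR: 0.07
  ABS: 1.0e-3
  PEF: 1.36e+9
child:
  IngR: [140.0, 200.0, 260.0]
  InhR: [5.25, 7.5, 9.75]
  BW: [15.4, 19.2, 23.0]
  ED: 6
  EF: 350
  AT_nc: 2190
  AT_ca: 25550
  SA: 2800
  SSAR: 0.2
  ABS: 1.0e-3
  PEF: 1.36e+9
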
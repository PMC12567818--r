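# Toxicity values per metal and exposure pathway, standards-derived
# (USEPA IRIS / regional screening level conventions), fully overridable.
# rfd: reference dose, mg/(kg d); sf: carcinogenic slope factor, (kg d)/mg.
# A missing entry means no value is in use for that metal x pathway: the
# hazard quotient set is {Cd, Ni, As, Zn, Cu, Cr} and the carcinogenic set
# is {Cd, Ni, As, Pb}.
Cd:
  rfd: {ingestion: 1.0e-3, inhalation: 1.0e-3, dermal: 1.0e-5}
  sf: {ingestion: 6.1, inhalation: 6.3}
Ni:
  rfd: {ingestion: 2.0e-2, inhalation: 2.06e-2, dermal: 5.4e-3}
  sf: {inhalation: 0.84}
As:
  rfd: {ingestion: 3.0e-4, inhalation: 3.01e-4, dermal: 1.23e-4}
  sf: {ingestion: 1.5, inhalation: 15.1, dermal: 3.66}
Pb:
  sf: {ingestion: 8.5e-3, inhalation: 4.2e-2}
Zn:
  rfd: {ingestion: 3.0e-1, inhalation: 3.0e-1, dermal: 6.0e-2}
Cu:
  rfd: {ingestion: 4.0e-2, inhalation: 4.02e-2, dermal: 1.2e-2}
Cr:
  rfd: {ingestion: 3.0e-3, inhalation: 2.86e-5, dermal: 6.0e-5}
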
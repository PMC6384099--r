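# Reference batch cultures of C. beijerinckii DSM 6423 (bioreactor, CM2
# medium, 37 C, no pH control).  Start and end concentrations in mM; "ND"
# marks below-detection.  Acetate is dosed at t0 (the medium contains
# ammonium acetate) and can end as net substrate or net product.  Biomass
# end points are mM of the 5-carbon formula unit C5H9O2.5N.
glucose:
  file: table1_glucose.csv
  duration_h: 56
  substrates: [glucose, acetate]
  biomass_end_mM: 26.6
  pathway: glucose
rhamnose:
  file: table1_rhamnose.csv
  duration_h: 56
  substrates: [rhamnose, acetate]
  biomass_end_mM: 2.1
  pathway: rhamnose
mixture:
  file: table1_mixture.csv
  duration_h: 72
  substrates: [glucose, rhamnose, acetate]
  biomass_end_mM: 11.7
  pathway: mixture
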
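# Packaged data

`grp1_table1_synthetic_calibration.csv`

- The 18 `protein` rows transcribe the published accessibility table for the
  spin-labeled GRP1 PH domain mutants: O2 and NiEDDA collision parameters
  with SEMs, plus the printed depth parameter (`phi_printed`) and its
  printed SEM for cross-checking the ln-ratio computation.
- The 4 `calibration` rows are SYNTHETIC stand-ins: the source study used
  5-/7-/10-/12-doxyl-PC calibration lipids but printed neither their
  accessibility parameters nor their depths. Depths here are plausible
  doxyl-scale values ({-8, -11, -13, -16} Angstrom below the mean phosphate
  plane) and the collision parameters were generated from the package's
  default hyperbola at those depths. They exist so the full table contract
  (18 protein + 4 calibration rows) is exercised; they carry no
  experimental information.

`pipeline_synthetic.yaml` — example configuration running the pipeline
end-to-end on the synthetic generator.
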
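# End-to-end pipeline on the synthetic study design (18 protein label
# sites + 4 calibration lipids). Outputs land in out_dir.
simulate: true
n_sites: 18
sigma_phi: 0.02
seed: 1
contact_cutoff: 3.0
out_dir: "pipeline_out"
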
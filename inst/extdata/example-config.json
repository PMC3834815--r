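{
  "channels": 1024,
  "window_ns": 25,
  "irf": { "fwhm_ps": 80, "t0_ns": 2 },
  "wavelengths": [370, 380, 390],
  "peak_counts": 10000,
  "background": 0,
  "conditions": [
    { "name": "substrate", "preset": "double_flap", "unpaired_fraction": 0.0 },
    { "name": "y40a_complex", "preset": "y40a_substrate", "unpaired_fraction": 0.83 }
  ],
  "reference": "substrate",
  "mixture_refs": { "ds": "duplex", "ss": "single_strand" },
  "cd": { "noise_sd": 0.2, "n_scans": 5, "baseline_coeffs": [0.3, -0.2] },
  "dna_conc_M": 1e-05,
  "residues_2ap": 2,
  "pathlength_cm": 1,
  "smoothing_width": 5,
  "n_components": 4,
  "max_components": 5,
  "alpha": 0.05,
  "n_boot": 0,
  "seed": 1234,
  "outdir": "stackprobe-out"
}
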
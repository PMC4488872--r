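# UVC-dose calibration on a synthetic dose series: one DNA concentration,
# five doses, eight replicates per dose
task: regression
response: uvc_dose
models: [plsr, pcr]
wavelength_range: [1300, 1600]
smoothing_points: 21
smoothing_method: moving_average
osc_components: 1
validation: loo
seed: 7
synthetic:
  seed: 7
  n_per_group: 8
  design:
    dna_conc: [20, 20, 20, 20, 20]
    uvc_dose: [0, 5, 10, 15, 20]
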
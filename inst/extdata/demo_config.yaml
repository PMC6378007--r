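# Demonstration run: one gene pair, two conditions.
# Injected colocalization probabilities follow the published effect sizes
# (emulation presets); observed percentages additionally include the
# geometric background of random proximity (~28% for this nucleus size).
experiment: demo
seed: 1
optics:
  nx: 64
  ny: 64
  nz: 64
  dx: 0.25
  dy: 0.25
  dz: 0.2
  psf_sigma_lateral: 0.2
  psf_sigma_axial: 0.5
  noise_model: poisson
shape:
  semi_axes: [5.0, 4.2, 3.5]
  deformation_amplitude: 0.1
  n_nucleoli: 2
genes:
  - {gene: POU5F1, channel: green, copies: 2}
  - {gene: CDYL, channel: red, copies: 2}
pairs:
  - "POU5F1:CDYL"
conditions:
  - name: pluripotent
    n_nuclei: 30
    coloc: {"POU5F1:CDYL": 0.385}
  - name: differentiated
    n_nuclei: 30
    coloc: {"POU5F1:CDYL": 0.30}
    volume_scale: 0.928
interaction:
  threshold_um: 2.0
  metric: per_nucleus_min
  histogram_bins: 14
  bin_width_um: 1.0
null_model:
  radius_um: 4.23
  n_draws: 50000
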
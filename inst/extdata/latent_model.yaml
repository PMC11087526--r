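# Five-dimension latent measurement model of song style.
#
# Each indicator loads on exactly one latent; latents are free to
# correlate; six residual covariances absorb indicator pairs whose
# association is not explained by the latents. The indicator lists are
# editable defaults paired with the shipped coding scheme.
latents:
  Articulation: [line_8, line_9, line_10, line_12, line_14]
  Tension: [line_33, line_34, line_35, line_36, line_37]
  Ornamentation: [line_17, line_23, line_25, line_31, line_32]
  Rhythm: [line_11, line_13, line_20, line_21]
  Dynamics: [line_6, line_26, line_28, line_29, line_30]
residual_covariances:
  - [line_8, line_9]
  - [line_33, line_34]
  - [line_17, line_25]
  - [line_11, line_13]
  - [line_26, line_28]
  - [line_36, line_37]
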
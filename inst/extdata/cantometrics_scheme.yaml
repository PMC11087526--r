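# Coding scheme for the 24-feature ordinal song-style battery.
#
# Per feature: the ordered code set (the full 13-point coding scale here;
# non-consecutive subsets are equally valid and are rank-interpolated), whether the scale is reversed
# so that high values mean "more of" the named trait, an inter-rater
# reliability kappa, and an include flag. The 24-of-37 subset, the
# reversal list and the kappas shipped here are editable defaults meant
# to be replaced with a study's own variable table; the structure, not
# the particular list, is what the pipeline consumes.
#
# `keep` lists features retained by reliability filtering regardless of
# kappa (kept for their importance to model convergence).
features:
  # Articulation block (lyric repetition and enunciation)
  line_8:  {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.71, include: true}
  line_9:  {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: true,  kappa: 0.58, include: true}
  line_10: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.66, include: true}
  line_12: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.52, include: true}
  line_14: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.47, include: true}
  # Tension block (vocal width, nasality, raspiness)
  line_33: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.49, include: true}
  line_34: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: true,  kappa: 0.44, include: true}
  line_35: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.35, include: true}
  line_36: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.41, include: true}
  line_37: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.12, include: true}
  # Ornamentation block (decorative singing)
  line_17: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.63, include: true}
  line_23: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: true,  kappa: 0.55, include: true}
  line_25: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.61, include: true}
  line_31: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.20, include: true}
  line_32: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.57, include: true}
  # Rhythm block (meter and tempo)
  line_11: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.72, include: true}
  line_13: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.38, include: true}
  line_20: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.68, include: true}
  line_21: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.59, include: true}
  # Dynamics block (volume, register, intensity)
  line_6:  {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.64, include: true}
  line_26: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: true,  kappa: 0.53, include: true}
  line_28: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.62, include: true}
  line_29: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.48, include: true}
  line_30: {codes: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13], reversed: false, kappa: 0.45, include: true}
keep:
  - line_31
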
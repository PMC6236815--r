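# Default replan violation criteria shipped with artflag.
#
# RECONSTRUCTION NOTICE: the institutional survey-derived criteria table is
# not fully recoverable. Anchored values: the spinal-cord Dmax planning
# objective of 48 Gy with a 3% major overdose margin (threshold 49.4 Gy).
# GTV/CTV criteria are copied from the PTV criteria (no formal planning
# objectives exist for GTV/CTV); target coverage and brainstem/spinal-cord
# sparing are major-class; target hot spot and parotid sparing are
# minor-class. Percent margins without a recoverable value (target coverage
# 5%, hot spot 5%, parotid 10%) and the brainstem objective (54 Gy) are
# package reconstructions. Optic structures are major-class criteria
# clinically; they are omitted here because the default phantom has no
# optic structures (add entries with class: major to grade them).
#
# reference: a number (Gy) or "planned" = the course's planned parameter
# value. direction: limit (violation above reference*(1+v/100)) or coverage
# (violation below reference*(1-v/100)).
criteria:
- parameter: cord_dmax
  structure: spinal_cord
  reference: 48.0
  direction: limit
  class: major
  v_major: 3.0
- parameter: brainstem_dmax
  structure: brainstem
  reference: 54.0
  direction: limit
  class: major
  v_major: 3.0
- parameter: gtv_high_d99
  structure: gtv_high
  reference: planned
  direction: coverage
  class: major
  v_major: 5.0
- parameter: ctv_high_d99
  structure: ctv_high
  reference: planned
  direction: coverage
  class: major
  v_major: 5.0
- parameter: ctv_low_d99
  structure: ctv_low
  reference: planned
  direction: coverage
  class: major
  v_major: 5.0
- parameter: ptv_high_d95
  structure: ptv_high
  reference: planned
  direction: coverage
  class: major
  v_major: 5.0
- parameter: ptv_low_d95
  structure: ptv_low
  reference: planned
  direction: coverage
  class: major
  v_major: 5.0
- parameter: ptv_high_dmax
  structure: ptv_high
  reference: planned
  direction: limit
  class: minor
  v_minor: 5.0
- parameter: parotid_left_dmean
  structure: parotid_left
  reference: planned
  direction: limit
  class: minor
  v_minor: 10.0
- parameter: parotid_right_dmean
  structure: parotid_right
  reference: planned
  direction: limit
  class: minor
  v_minor: 10.0
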
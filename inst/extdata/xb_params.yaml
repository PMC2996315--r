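# Cross-bridge spring parameters.
#
# Torsional rest values in degrees, stiffness pN nm/rad; extensional/axial
# rest values in nm, stiffness pN/nm. rest_pre applies in states 1-2,
# rest_post in state 3 (post power stroke). "derived" rest values are
# computed so the 2sXB tip matches the 4sXB tip in both rest conformations.
models:
  4sXB:
    tau: 12.0
    springs:
      - label: base_angle       # S2 / thick-filament rod junction
        kind: torsional
        rest_pre: 40.0
        rest_post: 40.0
        stiffness: 100.0
      - label: s2_length        # S2 segment
        kind: extensional
        rest_pre: 10.5
        rest_post: 10.5
        stiffness: 10.0
      - label: converter_angle  # S2 / light-chain-domain link; drives the stroke
        kind: torsional
        rest_pre: 125.0
        rest_post: 70.0
        stiffness: 40.0
      - label: lcd_length       # light-chain domain (lever arm)
        kind: extensional
        rest_pre: 9.6
        rest_post: 9.6
        stiffness: 5.0
  2sXB:
    tau: 72.0
    derive_rest_from: 4sXB
    springs:
      - label: base_angle       # torsional spring at the thick filament
        kind: torsional
        rest_pre: derived       # ~47.16 deg; 73.20 deg post stroke
        rest_post: derived
        stiffness: 40.0
      - label: arm_length       # extensional lever arm
        kind: extensional
        rest_pre: derived       # ~19.93 nm; 16.47 nm post stroke
        rest_post: derived
        stiffness: 2.0
  1sXB:
    springs:
      - label: axial_spring     # classic single spring along the filament axis
        kind: axial
        rest_pre: 5.0
        rest_post: 0.0
        stiffness: 5.0
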
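# Segment definition for human cannabinoid receptor 1 (CB1).
#
# BW anchors and pivot prolines are literature residues: D163 carries 2.50,
# the CWxP proline P358 carries 6.50 and splits TM6, and the NPxxY proline
# P394 carries 7.50 and splits TM7.  The TM first/last residues below are
# APPROXIMATE reconstructions from canonical class-A helix spans around those
# anchors, not an authoritative assignment; adjust to your own secondary-
# structure analysis before quantitative per-segment work.
segments:
  Nterm: [90, 115]
  TM1: [116, 145]
  ICL1: [146, 149]
  TM2: [150, 180]
  ECL1: [181, 186]
  TM3: [187, 222]
  ICL2: [223, 232]
  TM4: [233, 256]
  ECL2: [257, 268]
  TM5: [269, 298]
  ICL3: [299, 336]
  TM6: [337, 366]
  ECL3: [367, 373]
  TM7: [374, 402]
pivots:
  TM6: 358
  TM7: 394
bw_anchors:
  "1": 134
  "2": 163
  "3": 214
  "4": 241
  "5": 286
  "6": 358
  "7": 394
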
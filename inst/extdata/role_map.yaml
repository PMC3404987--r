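DOPC:
- PHOSPHATE_MARKER
- PHOSPHATE_MARKER
- HEAD_OTHER
- HEAD_OTHER
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
- TAIL_CARBON
CHOL:
- CHOL_HYDROXYL_O
- CHOL_HYDROXYL_O
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
- HEAD_OTHER
WATER:
- WATER_O
- WATER_O
- WATER_O
- WATER_H
- WATER_H
- WATER_H
- WATER_H
DMSO:
- DMSO_S
- DMSO_S
- DMSO_O
- DMSO_O
- DMSO_C
- DMSO_C
- DMSO_C
- DMSO_C
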
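# Default torsion library.
# One rule per line: a 4-atom SMARTS pattern, then the allowed torsion
# angles in degrees (values in [0, 360)). The driven bond is the pattern's
# 2nd-3rd atom pair; the first matching line wins. Bonds matching no rule
# fall back to the 12-angle 30-degree grid.
#
# These angle sets are this package's own defaults and are meant to be
# replaced by users with domain-specific libraries where needed.

# amide C-N: planar, cis/trans
[OX1]=[CX3]-[NX3][!#1]    0 180
# ester C-O: planar, cis/trans
[OX1]=[CX3]-[OX2][!#1]    0 180
# sp3-sp3 single bond: full 30-degree grid
[!#1][CX4]-[CX4][!#1]     0 30 60 90 120 150 180 210 240 270 300 330
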
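para-difluorobenzene
     RDKit          3D

 12 12  0  0  0  0  0  0  0  0999 V2000
    1.3900    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6950    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6950    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3900    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6950   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6950   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7400    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7400    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0
    1.2350    2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2350    2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2350   -2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2350   -2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
  1  7  1  0
  4  8  1  0
  2  9  1  0
  3 10  1  0
  5 11  1  0
  6 12  1  0
M  END
$$$$
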
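tert-butylbenzene
     RDKit          3D

 24 24  0  0  0  0  0  0  0  0999 V2000
    1.3900    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6950    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6950    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3900    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6950   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6950   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4100    0.0000    1.4425 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4100    1.2492   -0.7212 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4100   -1.2492   -0.7212 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0467   -0.8900    1.9563 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5000   -0.0000    1.4425 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0467    0.8900    1.9563 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0467    2.1392   -0.2074 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5000    1.2492   -0.7212 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0467    1.2492   -1.7489 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0467   -1.2492   -1.7489 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5000   -1.2492   -0.7212 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0467   -2.1392   -0.2074 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2350    2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2350    2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4700    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2350   -2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2350   -2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
  1  7  1  0
  7  8  1  0
  7  9  1  0
  7 10  1  0
  8 11  1  0
  8 12  1  0
  8 13  1  0
  9 14  1  0
  9 15  1  0
  9 16  1  0
 10 17  1  0
 10 18  1  0
 10 19  1  0
  2 20  1  0
  3 21  1  0
  4 22  1  0
  5 23  1  0
  6 24  1  0
M  END
$$$$
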
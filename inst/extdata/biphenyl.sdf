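biphenyl
     RDKit          3D

 22 23  0  0  0  0  0  0  0  0999 V2000
   -0.7400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4350    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8250    1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5200    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8250   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4350   -1.2038    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4350   -0.8659   -0.8362 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8250   -0.8659   -0.8362 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5200   -0.0000   -0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8250    0.8659    0.8362 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4350    0.8659    0.8362 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8950    2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3650    2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3650   -2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8950   -2.1391    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8950   -1.5387   -1.4859 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3650   -1.5387   -1.4859 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.6000   -0.0000   -0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3650    1.5387    1.4859 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8950    1.5387    1.4859 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10 11  1  0
 11 12  2  0
 12  7  1  0
  1  7  1  0
  2 13  1  0
  3 14  1  0
  4 15  1  0
  5 16  1  0
  6 17  1  0
  8 18  1  0
  9 19  1  0
 10 20  1  0
 11 21  1  0
 12 22  1  0
M  END
$$$$
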
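butane
     RDKit          3D

 14 13  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2492    0.0000    0.8833 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4985    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7477    0.0000    0.8833 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000   -0.8900   -0.6293 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8900   -0.0000    0.6293 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0000    0.8900   -0.6293 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7477   -0.8900    1.5127 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.6377   -0.0000    0.2540 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7477    0.8900    1.5127 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2492   -0.8900    1.5127 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2492    0.8900    1.5127 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4985    0.8900   -0.6293 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4985   -0.8900   -0.6293 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  1  5  1  0
  1  6  1  0
  1  7  1  0
  4  8  1  0
  4  9  1  0
  4 10  1  0
  2 11  1  0
  2 12  1  0
  3 13  1  0
  3 14  1  0
M  END
$$$$
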
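sulfone-analogue
     RDKit          3D

 27 27  0  0  0  0  0  0  0  0999 V2000
    4.8793    0.0885    0.4229 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.8744    1.0587   -0.1685 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5386    0.6485    0.1628 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.9495   -0.2246   -0.6964 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4945   -0.7317   -1.6685 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.5659   -0.5536   -0.2641 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4857    0.8076   -0.6483 S   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2382    1.8860    0.2901 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4605    1.0454   -2.0787 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1003    0.1583   -0.2642 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6224    0.3250    1.0216 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.8868   -0.1838    1.3168 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6227   -0.8440    0.3310 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1019   -0.9921   -0.9559 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8385   -0.4865   -1.2607 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.7386    0.0017    1.5053 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.7505   -0.9145    0.0040 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.9022    0.4210    0.2254 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.0208    2.0527    0.2665 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.0028    1.1588   -1.2524 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2186   -1.4330   -0.8139 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5346   -0.7645    0.8075 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0630    0.8533    1.7908 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3053   -0.0579    2.3128 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.6114   -1.2338    0.5630 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.6868   -1.4937   -1.7235 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4469   -0.5917   -2.2704 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  2  0
  4  6  1  0
  6  7  1  0
  7  8  2  0
  7  9  2  0
  7 10  1  0
 10 11  2  0
 11 12  1  0
 12 13  2  0
 13 14  1  0
 14 15  2  0
 15 10  1  0
  1 16  1  0
  1 17  1  0
  1 18  1  0
  2 19  1  0
  2 20  1  0
  6 21  1  0
  6 22  1  0
 11 23  1  0
 12 24  1  0
 13 25  1  0
 14 26  1  0
 15 27  1  0
M  END
$$$$
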
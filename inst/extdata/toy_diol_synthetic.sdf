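toy diol (synthetic fixture)
  hbnetforge

  7  6  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5300    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4735    1.3388    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4504    1.3503    0.0676 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0035    0.6694    1.1594 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.9757    0.6234    1.1986 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5101   -0.6694   -1.2479 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  1  3  1  0
  3  4  1  0
  2  5  1  0
  5  6  1  0
  1  7  1  0
M  END
$$$$
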
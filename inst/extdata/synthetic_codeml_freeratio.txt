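CODONML (in paml)  synthetic free-ratio (M1) main result for one gene
This file is a synthetic example of the per-branch dN/dS table layout; the
values are invented for format testing and do not derive from any alignment.

((Dmel, Dsim), Dyak, Dana);

tree length =  0.8421

 branch          t       N       S   dN/dS      dN      dS  N*dN  S*dS
   5..1      0.048   912.4   310.6  0.2216  0.0092  0.0415   8.4  12.9
   5..2      0.052   912.4   310.6  0.1778  0.0080  0.0450   7.3  14.0
   6..3      0.131   912.4   310.6  0.1569  0.0170  0.1083  15.5  33.6
   6..4      0.388   912.4   310.6  0.2485  0.0861  0.3465  78.6 107.6
   6..5      0.041   912.4   310.6  0.1995  0.0079  0.0396   7.2  12.3
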
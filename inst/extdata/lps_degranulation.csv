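name,0h,2h,4h,6h,12h,24h
CD63,1.00 ± 0.42,1.09 ± 0.33,0.97 ± 0.10,1.02 ± 0.12,0.88 ± 0.10,0.92 ± 0.12
CD15,1.00 ± 0.07,1.08 ± 0.14,1.26 ± 0.06,1.23 ± 0.07,1.56 ± 0.13,1.36 ± 0.16
CD66b,1.00 ± 0.06,1.14 ± 0.13,1.37 ± 0.12,1.72 ± 0.14,2.41 ± 0.13,1.87 ± 0.20
CD11b,1.00 ± 0.17,1.29 ± 0.14,1.62 ± 0.09,2.11 ± 0.21,2.57 ± 0.29,2.03 ± 0.34
CD13,1.00 ± 0.13,1.08 ± 0.10,1.14 ± 0.13,1.38 ± 0.14,1.94 ± 0.31,1.76 ± 0.32
CD14,1.00 ± 0.30,1.13 ± 0.33,1.31 ± 0.37,1.58 ± 0.44,1.23 ± 0.35,1.00 ± 0.31
CD18,1.00 ± 0.14,1.26 ± 0.26,1.23 ± 0.17,1.61 ± 0.3,2.22 ± 0.33,1.68 ± 0.27
CD45,1.00 ± 0.12,1.19 ± 0.15,1.39 ± 0.11,1.58 ± 0.16,2.18 ± 0.10,1.84 ± 0.22
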
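name,0h,2h,4h,6h,12h,24h
TNFα,1.28 ± 0.28,6.30 ± 1.81,24.82 ± 8.26,51.54 ± 14.79,36.70 ± 11.20,16.48 ± 11.35
IL1α,0.73 ± 0.38,1.43 ± 0.21,3.36 ± 1.92,6.84 ± 4.92,6.67 ± 3.51,14.70 ± 8.51
IL1β,0.69 ± 0.69,1.64 ± 0.2,4.87 ± 2.55,8.45 ± 5.89,7.89 ± 2.3,4.20 ± 3.46
IL6,0.93 ± 0.18,1.30 ± 0.37,34.35 ± 23.38,69.92 ± 50.91,185.53 ± 62.99,23.64 ± 10.51
IL12β,1.02 ± 0.06,0.88 ± 0.04,1.06 ± 0.09,1.16 ± 0.19,6.20 ± 3.57,1.08 ± 0.25
CCL2,0.97 ± 0.13,0.86 ± 0.17,1.11 ± 0.18,1.17 ± 0.36,6.43 ± 1.48,1.69 ± 0.66
CCL3,1.43 ± 1.43,6.72 ± 0.98,24.35 ± 4.51,66.06 ± 17.86,65.98 ± 24.41,11.05 ± 4.62
CCL4,1.06 ± 0.07,2.65 ± 0.76,8.10 ± 3.09,11.69 ± 5.84,69.14 ± 15.76,1.22 ± 0.72
CCL5,0.88 ± 0.05,1.07 ± 0.24,1.04 ± 0.34,0.89 ± 0.22,0.96 ± 0.18,1.05 ± 0.29
IL8,1.02 ± 0.12,4.89 ± 1.47,9.85 ± 2.31,15.84 ± 3.93,31.83 ± 10.15,27.00 ± 8.89
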
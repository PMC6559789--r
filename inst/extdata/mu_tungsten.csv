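"E_keV","mu_over_rho_cm2_g"
8,181.02
9,130.16
10,96.91
10.2068,91.512
10.2068,233.4
10.5,216.22
11,190.7
11.544,167.39
11.544,238.3
12,214.63
12.0998,209.89
12.0998,250.7
12.5,229.25
13,205.83
13.5,185.55
14,167.9
14.5,152.46
15,138.9
16,117.44
17,100.31
18,86.451
19,75.11
20,65.73
22,51.211
24,40.775
26,33.064
28,27.231
30,22.73
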
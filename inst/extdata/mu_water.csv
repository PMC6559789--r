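"E_keV","mu_over_rho_cm2_g"
8,10.37
8.5,8.6542
9,7.2973
9.5,6.2102
10,5.329
10.5,4.6355
11,4.0586
11.5,3.5745
12,3.1652
12.5,2.8167
13,2.5181
13.5,2.2607
14,2.0376
14.5,1.8432
15,1.673
16,1.4216
17,1.22
18,1.0561
19,0.92146
20,0.8096
22,0.67587
24,0.57318
26,0.49254
28,0.42804
30,0.3756
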
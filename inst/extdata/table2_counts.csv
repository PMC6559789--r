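region,specimen_1,specimen_2,specimen_3,specimen_4,specimen_5
Olfactory Epithelium,855,398,1103,1158,1257
Telencephalon,3696,4735,4576,3704,4570
Diencephalon,6323,6076,7390,7718,8134
Hypothalamus,2096,2342,3392,3047,2680
Mesencephalon,17377,15993,21161,21448,22275
Metencephalon,876,1025,1012,2865,1713
Myelencephalon,27899,28691,30991,37769,34766
White Matter,5633,5955,5810,4524,5181
Spinal Cord,1408,1570,1850,1712,2312
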
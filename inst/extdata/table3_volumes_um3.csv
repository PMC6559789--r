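region,specimen_1,specimen_2,specimen_3,specimen_4,specimen_5
Olfactory Epithelium,293251,171459,164338,131459,111195
Telencephalon,1117500,1021518,956493,826273,672572
Diencephalon,1440447,1300518,1097698,1134753,1046486
Hypothalamus,813210,702116,732073,608018,575387
Mesencephalon,4353108,3442415,3663909,3183413,2885684
Metencephalon,324562,273699,388409,529656,296336
Myelencephalon,4982069,4636451,3977877,4550207,3850373
White Matter,4783477,4358188,4119302,3963126,3529787
Spinal Cord,78092,97609,117260,109808,125722
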
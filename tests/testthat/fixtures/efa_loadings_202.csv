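0.726254387154,0.095172368411
0.124887652846,-0.931745915209
-0.710348366349,-0.075479617105
-0.946171045923,-0.068926689407
0.897716663255,-0.112663157555
-0.868146356321,0.023386726293
-0.739061709276,-0.205687781126
0.123272588495,-0.828751301962
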
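1.000000000000,0.448893128566,-0.423655165729,-0.135666127812,0.391572671211,-0.139720375981,0.730537315529,-0.388370825575,0.406315848497,0.844312580088
0.448893128566,1.000000000000,-0.893929381434,-0.006074874373,0.818303555166,0.100733060972,0.049666423614,0.441081770138,0.730806133209,0.159312719103
-0.423655165729,-0.893929381434,1.000000000000,-0.046789259069,-0.844010397449,-0.158770638469,0.001864833290,-0.442991973830,-0.735775732443,-0.127048675857
-0.135666127812,-0.006074874373,-0.046789259069,1.000000000000,0.298552026427,0.675970399228,-0.448878448070,-0.163000586631,0.055639507639,-0.191231058759
0.391572671211,0.818303555166,-0.844010397449,0.298552026427,1.000000000000,0.415770116718,-0.129343748672,0.283186217476,0.702731547877,0.103636077937
-0.139720375981,0.100733060972,-0.158770638469,0.675970399228,0.415770116718,1.000000000000,-0.521540941039,-0.074358751163,0.143759415899,-0.239975889860
0.730537315529,0.049666423614,0.001864833290,-0.448878448070,-0.129343748672,-0.521540941039,1.000000000000,-0.470320093908,0.046256928154,0.828980936982
-0.388370825575,0.441081770138,-0.442991973830,-0.163000586631,0.283186217476,-0.074358751163,-0.470320093908,1.000000000000,0.294352395350,-0.594375806057
0.406315848497,0.730806133209,-0.735775732443,0.055639507639,0.702731547877,0.143759415899,0.046256928154,0.294352395350,1.000000000000,0.169907117320
0.844312580088,0.159312719103,-0.127048675857,-0.191231058759,0.103636077937,-0.239975889860,0.828980936982,-0.594375806057,0.169907117320,1.000000000000
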
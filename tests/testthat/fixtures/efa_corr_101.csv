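1.000000000000,0.407572775945,-0.599173804975,-0.512005545744,-0.378253916881,0.661295659553
0.407572775945,1.000000000000,-0.364125224049,-0.311152010503,-0.229869515470,0.401877432222
-0.599173804975,-0.364125224049,1.000000000000,0.457425385262,0.337931776509,-0.590801065257
-0.512005545744,-0.311152010503,0.457425385262,1.000000000000,0.288769205562,-0.504850878546
-0.378253916881,-0.229869515470,0.337931776509,0.288769205562,1.000000000000,-0.372968269266
0.661295659553,0.401877432222,-0.590801065257,-0.504850878546,-0.372968269266,1.000000000000
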
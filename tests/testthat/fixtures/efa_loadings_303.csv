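0.612641473670,-0.702349720470,-0.177130728611
0.920907607089,0.120426105500,0.173385069511
-0.924462307855,-0.171241209286,-0.126672372812
0.064932102957,0.419008050765,-0.670939262758
0.889818387456,0.267085483114,-0.192064006199
0.168209128995,0.514592119676,-0.669851968847
0.156097859116,-0.930031040095,0.103323392258
0.273075887755,0.624813608208,0.659573731698
0.773929215880,0.085178325118,0.045166156514
0.327195721500,-0.860983762197,-0.221007431205
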
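1.000000000000,0.001611448240,-0.523074175019,-0.693722853331,0.641260293667,-0.628280673074,-0.556288778645,0.011106133938
0.001611448240,1.000000000000,-0.018116106765,-0.053823353134,0.218317806952,-0.130758968787,0.100585981943,0.787711959755
-0.523074175019,-0.018116106765,1.000000000000,0.677317651886,-0.629194525610,0.614930731133,0.540491079585,-0.025308482749
-0.693722853331,-0.053823353134,0.677317651886,1.000000000000,-0.841628391618,0.819813545868,0.713436362942,-0.059643609573
0.641260293667,0.218317806952,-0.629194525610,-0.841628391618,1.000000000000,-0.781952503216,-0.640330747159,0.202661549386
-0.628280673074,-0.130758968787,0.614930731133,0.819813545868,-0.781952503216,1.000000000000,0.636816245225,-0.125795205242
-0.556288778645,0.100585981943,0.540491079585,0.713436362942,-0.640330747159,0.636816245225,1.000000000000,0.077979691654
0.011106133938,0.787711959755,-0.025308482749,-0.059643609573,0.202661549386,-0.125795205242,0.077979691654,1.000000000000
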
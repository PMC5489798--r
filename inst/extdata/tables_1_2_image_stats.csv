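image,sd_printed,eavg_printed
im0002.ah.jpg,0.0162,0.0211
im0139.ah.jpg,0.1094,0.2390
im0077.ah.jpg,0.1401,0.2752
10_h.tif,0.0234,0.0307
02_h.tif,0.0092,0.0161
15_h.tif,0.0063,0.0090
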
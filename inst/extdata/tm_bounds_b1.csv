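tm,lo,up,init,unit
Ca,0.30,4.0,3.0,g/L
K,0.32,4.2,3.2,g/L
Mg,0.08,1.8,0.80,g/L
Na,0.03,0.80,0.30,g/L
Fe,0.011,5.11,0.11,g/L
Co,0.002,0.12,0.02,g/L
Cr,0.30,103.0,3.0,mg/L
Ni,0.10,101.0,1.0,mg/L
Pb,0.02,100.2,0.20,mg/L
Cu,1.0,110.0,10.0,mg/L
Zn,5.0,150.0,50.0,mg/L
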
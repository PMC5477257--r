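feature,b,se,wald,p
uniformity,-105.5,109.2,0.93,0.334
entropy,0.3240,0.333,0.95,0.330
dissimilarity,-0.1292,0.065,4.01,0.045
correlation,4.013,2.195,3.34,0.068
idn,71.81,36.04,3.97,0.046
tumor_size,0.000627,0.00123,0.26,0.611
tumor_intensity,-0.011,0.013,0.82,0.366
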
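risk_factor,2,3,4,5,6,7,1&9
DM,0.85,0.89,0.82,0.85,0.82,0.76,0.82
HT,0.76,0.76,0.76,0.74,0.80,0.77,0.76
HC,0.81,0.73,0.78,0.75,0.73,0.66,0.69
CS,0.69,0.72,0.82,0.71,0.70,0.60,0.34
CD,0.81,0.85,0.82,0.80,0.81,0.74,0.82
OB,0.78,0.85,0.88,0.73,0.68,0.75,0.73
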
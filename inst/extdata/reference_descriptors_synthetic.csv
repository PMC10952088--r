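temperature,r_max1,g_max1,r_min1,g_min1
268,2.804,2.95,3.31,0.80
278,2.806,2.84,3.33,0.84
288,2.808,2.74,3.35,0.88
298,2.810,2.65,3.37,0.92
308,2.812,2.57,3.39,0.96
318,2.814,2.50,3.41,1.00
328,2.816,2.44,3.43,1.04
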
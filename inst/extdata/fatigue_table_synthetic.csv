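# Synthetic S-N fatigue-failure probability surface for lumbar vertebrae.
# Constructed, not measured: probability = Phi((S - (95 - 12*log10(N))) / 12)
# with S the relative load (% of ultimate compressive strength) and N the
# cycle count, reproducing the log-linear S-N shape of cadaveric lumbar
# fatigue data with probit scatter; loads below 30% UCS are treated as the
# endurance region (probability 0) by the interpolator. Replace with a
# measured table via read_fatigue_table() for subject-specific work.
load,cycles,probability
30,1,0.0000
30,10,0.0000
30,100,0.0003
30,1000,0.0078
30,10000,0.0783
30,100000,0.3385
40,1,0.0000
40,10,0.0002
40,100,0.0049
40,1000,0.0567
40,10000,0.2798
40,100000,0.6615
50,1,0.0001
50,10,0.0030
50,100,0.0401
50,1000,0.2266
50,10000,0.5987
50,100000,0.8944
60,1,0.0018
60,10,0.0276
60,100,0.1797
60,1000,0.5332
60,10000,0.8607
60,100000,0.9814
70,1,0.0186
70,10,0.1393
70,100,0.4668
70,1000,0.8203
70,10000,0.9724
70,100000,0.9982
80,1,0.1056
80,10,0.4013
80,100,0.7734
80,1000,0.9599
80,10000,0.9970
80,100000,0.9999
90,1,0.3385
90,10,0.7202
90,100,0.9433
90,1000,0.9951
90,10000,0.9998
90,100000,1.0000
100,1,0.6615
100,10,0.9217
100,100,0.9922
100,1000,0.9997
100,10000,1.0000
100,100000,1.0000
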
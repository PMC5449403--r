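cluster,I,I-O,Oil,O-II,II,10m,30m,50m,100m,300m,500m,800m,1000m
Cluster 1,0.281,0.208,0.274,0.238,0.319,0.298,0.354,0.377,0.183,0.151,0.194,0.152,0.192
Cluster 2,0.078,0.160,0.090,0.143,0.021,0.201,0.216,0.239,0.403,0.435,0.431,0.470,0.369
Cluster 3,0.000,0.019,0.000,0.000,0.000,0.000,0.007,0.007,0.054,0.053,0.087,0.078,0.118
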
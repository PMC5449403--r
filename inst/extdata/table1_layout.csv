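transect_id,zone,distance_m,n_plots
I,pipeline_area,0,6
I-O,inter_pipeline,0,6
Oil,pipeline_area,0,6
O-II,inter_pipeline,0,6
II,pipeline_area,0,6
10m,distance,10,6
30m,distance,30,6
50m,distance,50,6
100m,distance,100,6
300m,distance,300,6
500m,distance,500,6
800m,distance,800,6
1000m,distance,1000,6
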
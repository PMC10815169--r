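female,male,f1_genotype,plant_height_cm,stem_height_cm,spike_stalk_length_cm,stalk_stem_ratio
A2V4A,SX44B,Dw1Dw1-dw2dw2-dw3dw3-dw4dw4,132.60,108.25,38.54,0.36
A2V4A,CS3541B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,220.11,189.33,72.33,0.38
A2V4A,TX623B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,206.67,178.01,52.67,0.30
A2V4A,TX3197B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,181.00,147.67,50.33,0.34
SX44A,A2V4B,Dw1Dw1-dw2dw2-dw3dw3-dw4dw4,130.26,102.53,37.25,0.36
SX44A,CS3541B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,175.22,149.52,50.12,0.34
SX44A,TX623B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,177.21,151.25,52.26,0.35
SX44A,TX3197B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,187.55,161.32,57.35,0.36
CS3541A,A2V4B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,217.00,176.67,67.00,0.38
CS3541A,SX44B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,177.32,150.23,52.12,0.35
CS3541A,TX623B,dw1dw1-Dw2DW2-dw3dw3-dw4dw4,164.33,133.00,66.01,0.50
CS3541A,TX3197B,dw1dw1-Dw2DW2-dw3dw3-dw4dw4,106.33,83.67,43.67,0.52
TX623A,A2V4B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,200.01,167.67,54.67,0.33
TX623A,SX44B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,182.21,150.23,49.52,0.33
TX623A,CS3541B,dw1dw1-Dw2DW2-dw3dw3-dw4dw4,154.67,124.67,67.67,0.54
TX623A,TX3197B,dw1dw1-Dw2DW2-dw3dw3-dw4dw4,140.33,114.33,40.01,0.35
TX3197A,A2V4B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,175.12,147.67,46.33,0.31
TX3197A,SX44B,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,168.41,140.12,44.21,0.32
TX3197A,CS3541B,dw1dw1-Dw2DW2-dw3dw3-dw4dw4,107.67,83.67,40.10,0.48
TX3197A,TX623B,dw1dw1-Dw2DW2-dw3dw3-dw4dw4,143.67,115.01,48.00,0.42
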
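female,male,f1_genotype,plant_height_cm
A2V4A,TX7078,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,192.33
A2V4A,SX1042,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,193.50
SX44A,TX7078,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,172.58
SX44A,SX1042,Dw1dw1-Dw2dw2-dw3dw3-dw4dw4,182.53
A2V4A,Jing liang 5,Dw1Dw1-Dw2dw2-dw3dw3-dw4dw4,232.40
A2V4A,SXR0-30,Dw1Dw1-Dw2dw2-dw3dw3-dw4dw4,220.67
SX44A,Jing liang 5,Dw1Dw1-Dw2dw2-dw3dw3-dw4dw4,202.15
SX44A,SXR0-30,Dw1Dw1-Dw2dw2-dw3dw3-dw4dw4,175.21
TX623A,TX7078,dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,133.33
TX623A,SX1042,dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,135.22
TX3197A,TX7078,dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,110.00
TX3197A,SX1042,dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,127.33
TX623A,Jing liang 5,Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,203.67
TX623A,SXR0-30,Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,194.33
TX3197A,Jing liang 5,Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,195.33
TX3197A,SXR0-30,Dw1dw1-Dw2Dw2-dw3dw3-dw4dw4,184.00
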
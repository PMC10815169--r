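name,line_type,subspecies,genotype,plant_height_cm,stem_height_cm,spike_stalk_length_cm,spike_length_cm,height_under_flag_leaf_cm,stalk_stem_ratio
SX44B,male_sterile,Durra,Dw1-dw2-dw3-dw4,115.00,88.67,39.00,26.33,49.67,0.44
SX4244B,male_sterile,Durra,Dw1-dw2-dw3-dw4,86.00,61.67,34.00,24.33,27.67,0.55
A2V4B,male_sterile,Durra,Dw1-dw2-dw3-dw4,126.33,101.33,37.33,25.00,64.00,0.37
1602N,restorer,Kaoliang/Caudatum,Dw1-dw2-dw3-dw4,115.00,88.00,30.67,27.00,57.33,0.35
2055B,male_sterile,Kafir/Durra,dw1-Dw2-dw3-dw4,70.33,52.00,30.33,18.33,21.67,0.58
L407B,male_sterile,Kafir/Durra,dw1-Dw2-dw3-dw4,103.00,76.00,41.67,27.00,34.33,0.55
TAM428B,male_sterile,Kafir/Durra,dw1-Dw2-dw3-dw4,98.33,68.33,30.00,30.00,38.33,0.44
SJB,male_sterile,Kafir/Complex,dw1-Dw2-dw3-dw4,126.33,100.33,44.67,26.00,55.67,0.45
L45B,male_sterile,Kafir/Complex,dw1-Dw2-dw3-dw4,144.33,107.67,44.67,36.67,63.00,0.41
N2B,male_sterile,Kafir/Durra,dw1-Dw2-dw3-dw4,107.00,72.33,39.00,34.67,33.33,0.54
[Tx623B.Bmr6/L199B]B,male_sterile,Kafir/Complex,dw1-Dw2-dw3-dw4,93.33,64.67,35.17,28.67,29.50,0.54
TX3197B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,115.00,94.00,44.00,21.00,50.00,0.47
[L45B/(TX623B/V4B)]B,male_sterile,Kafir/Complex,dw1-Dw2-dw3-dw4,117.00,79.00,39.83,38.00,39.17,0.50
(SX605B×L45B)B,male_sterile,Kafir/Complex,dw1-Dw2-dw3-dw4,132.33,106.00,37.33,26.33,68.67,0.35
(TXbmr6B/7501B)B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,108.67,80.67,42.00,28.00,38.67,0.52
N1B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,103.00,69.00,39.00,34.00,30.00,0.57
N3B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,116.33,84.00,50.17,32.33,33.83,0.60
J4190B,male_sterile,Kafir/Durra,dw1-Dw2-dw3-dw4,84.00,56.33,33.00,27.67,23.33,0.59
ZSB,male_sterile,Kafir,dw1-Dw2-dw3-dw4,127.67,103.67,48.33,24.00,55.33,0.47
TX414B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,87.00,64.00,34.00,23.00,30.00,0.53
TX639B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,132.50,108.33,49.00,24.17,59.33,0.45
TX649B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,124.00,84.67,41.33,39.33,43.33,0.49
TX623B,male_sterile,Kafir/Caudatum,dw1-Dw2-dw3-dw4,128.00,96.00,52.00,32.00,44.00,0.54
7501B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,104.33,84.00,43.50,20.33,40.50,0.52
7050B,male_sterile,Kafir/Complex,dw1-Dw2-dw3-dw4,128.50,95.50,37.00,33.00,58.50,0.39
TX2925B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,113.00,87.67,43.67,25.33,44.00,0.50
J16VII18B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,108.33,71.00,33.67,37.33,37.33,0.47
J16VII27B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,102.67,73.33,36.00,29.33,37.33,0.49
SX605B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,128.00,94.00,39.67,34.00,54.33,0.42
SX77B,male_sterile,Kafir,dw1-Dw2-dw3-dw4,104.00,70.33,44.33,33.67,26.00,0.63
CS3541B,male_sterile,Durra,dw1-Dw2-dw3-dw4,111.33,82.33,50.67,29.00,31.67,0.62
SX3142B,male_sterile,Kafir/kuban,dw1-Dw2-dw3-dw4,89.67,65.67,26.33,24.00,39.33,0.40
(314B/623B)B,male_sterile,Kafir/Caudatum,dw1-Dw2-dw3-dw4,112.67,88.00,39.67,24.67,48.33,0.45
LNR,restorer,Kaoliang/Caudatum,dw1-Dw2-dw3-dw4,131.67,108.67,20.67,23.00,88.00,0.19
XLH*GN2,restorer,Kaoliang/Caudatum,dw1-Dw2-dw3-dw4,104.00,78.67,29.00,25.33,49.67,0.37
0592F,restorer,Kaoliang/Caudatum,dw1-Dw2-dw3-dw4,92.17,63.17,37.10,29.00,26.07,0.59
TX7078,restorer,Kafir,dw1-Dw2-dw3-dw4,112.67,89.67,46.67,23.00,43.00,0.52
HTX430,restorer,Kafir,dw1-Dw2-dw3-dw4,108.00,74.00,44.25,34.00,29.75,0.60
TX432,restorer,Kafir,dw1-Dw2-dw3-dw4,91.00,67.00,44.00,24.00,23.00,0.66
TX414,restorer,Kafir/Durra,dw1-Dw2-dw3-dw4,87.33,66.67,36.67,20.67,30.00,0.55
TX2737,restorer,Kafir,dw1-Dw2-dw3-dw4,69.83,46.00,26.67,23.83,19.33,0.58
91633(H),restorer,Kafir,dw1-Dw2-dw3-dw4,97.67,74.33,37.83,23.33,36.50,0.51
91635(H),restorer,Kafir,dw1-Dw2-dw3-dw4,91.00,69.00,39.00,22.00,30.00,0.57
91644(H),restorer,Kafir,dw1-Dw2-dw3-dw4,103.50,74.50,46.00,29.00,28.50,0.62
91645(H),restorer,Kafir,dw1-Dw2-dw3-dw4,105.67,77.67,43.33,28.00,34.33,0.56
91648,restorer,Kafir,dw1-Dw2-dw3-dw4,94.33,70.33,42.33,24.00,28.00,0.60
SX1042,restorer,Kaoliang/Kafir,dw1-Dw2-dw3-dw4,107.00,74.33,38.67,32.67,35.67,0.52
961547,restorer,Kafir,dw1-Dw2-dw3-dw4,95.00,73.33,42.33,21.67,31.00,0.58
91624(H),restorer,Kafir,dw1-Dw2-dw3-dw4,92.50,63.07,39.17,29.43,23.90,0.62
SX861,restorer,Kaoliang/Caudatum,dw1-Dw2-dw3-dw4,97.67,68.67,19.33,29.00,49.33,0.28
NJ426,restorer,Kafir/Durra,dw1-dw2-Dw3-dw4,90.33,62.67,39.00,27.67,23.67,0.62
SX111B,male_sterile,Complex,dw1-Dw2-Dw3-dw4,97.33,74.67,37.50,22.67,37.17,0.50
998B,male_sterile,Kafir,dw1-Dw2-Dw3-dw4,117.67,91.67,49.17,26.00,42.50,0.54
961542B,male_sterile,Durra,dw1-Dw2-Dw3-dw4,95.67,69.00,47.00,26.67,22.00,0.68
Hegari,restorer,Caudatum,Dw1-dw2-Dw3-dw4,217.00,195.00,53.00,22.00,142.00,0.27
TV33B,male_sterile,Kafir,Dw1-Dw2-dw3-dw4,78.00,66.00,28.67,12.00,37.33,0.43
N4B,male_sterile,Kafir/Complex,Dw1-Dw2-dw3-dw4,143.67,102.67,43.67,41.00,59.00,0.43
F4B,male_sterile,Durra,Dw1-Dw2-dw3-dw4,153.50,126.00,32.50,27.50,93.50,0.26
HC356,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,157.00,129.00,33.33,28.00,95.67,0.26
1383-2,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,133.67,108.00,21.00,25.67,87.00,0.19
zhzy2-07,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,116.00,95.00,23.00,21.00,72.00,0.24
N133,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,118.00,99.00,26.50,19.00,72.50,0.27
363C/2691,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,136.33,117.67,27.67,18.67,90.00,0.24
J98H,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,126.00,91.33,28.33,34.67,63.00,0.31
F-R,restorer,Durra,Dw1-Dw2-dw3-dw4,104.00,80.33,42.67,23.67,37.67,0.53
JR108,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,130.67,99.33,39.33,31.33,60.00,0.40
X6936R,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,95.00,66.00,40.00,29.00,26.00,0.61
9198/TMS,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,110.00,74.00,33.67,36.00,40.33,0.46
IS7444C,restorer,Unknown,Dw1-Dw2-dw3-dw4,129.00,111.67,51.60,17.33,60.07,0.46
HBNR436-2,restorer,Kaoliang/Kafir,Dw1-Dw2-dw3-dw4,105.50,73.50,26.50,32.00,47.00,0.36
9825R-1,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,93.67,66.67,31.33,27.00,35.33,0.47
R111,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,137.50,113.00,26.00,24.50,87.00,0.23
XYLgaoliang,restorer,Unknown,Dw1-Dw2-dw3-dw4,137.67,110.33,32.33,27.33,78.00,0.29
HM65,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,161.33,136.33,37.00,25.00,99.33,0.27
LNH13,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,133.33,103.67,24.00,29.67,79.67,0.23
2381,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,134.00,110.00,26.50,24.00,83.50,0.24
XL7,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,142.33,118.67,34.33,23.67,84.33,0.29
Jing liang 5,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,138.00,109.73,26.83,28.27,82.90,0.24
SXR0-30,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,124.67,101.33,33.33,23.33,68.00,0.33
ZHOU,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,111.00,85.67,28.67,25.33,57.00,0.33
JR105,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,124.67,93.67,37.00,31.00,56.67,0.40
1603N,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,113.67,85.33,27.00,28.33,58.33,0.32
0-30/DHS,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,136.67,112.00,35.00,24.67,77.00,0.31
5564F,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,94.33,69.00,26.67,25.33,42.33,0.39
5577F,restorer,Kaoliang/Caudatum,Dw1-Dw2-dw3-dw4,100.67,73.67,29.67,27.00,44.00,0.40
LN8RN,restorer,Kaoliang/Caudatum,Dw1-Dw2-Dw3-dw4,128.33,106.33,28.67,22.00,77.67,0.27
XLH-1,restorer,Kaoliang/Caudatum,Dw1-Dw2-Dw3-dw4,179.00,153.67,35.00,25.33,118.67,0.23
Hong yin zi,restorer,Kaoliang,Dw1-Dw2-Dw3-dw4,247.33,228.00,48.33,19.33,179.67,0.21
Feterita,restorer,Unknown,Dw1-Dw2-Dw3-dw4,215.00,188.50,31.83,26.50,156.67,0.17
QKY,restorer,Kaoliang,Dw1-Dw2-Dw3-dw4,291.00,270.67,35.00,20.33,235.67,0.13
K35-Y5*1383,restorer,Complex,Dw1-Dw2-Dw3-dw4,101.33,78.00,21.67,23.33,56.33,0.28
JR107,restorer,Kaoliang/Caudatum,Dw1-Dw2-Dw3-dw4,120.67,87.33,35.50,33.33,51.83,0.41
chf5933,restorer,Kaoliang,Dw1-Dw2-Dw3-dw4,153.67,121.00,35.33,32.67,85.67,0.29
SCS,restorer,Kaoliang,Dw1-Dw2-Dw3-dw4,138.00,109.73,26.83,28.27,82.90,0.24
20131937,restorer,Kaoliang,Dw1-Dw2-Dw3-dw4,221.00,205.33,32.27,15.67,173.07,0.16
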
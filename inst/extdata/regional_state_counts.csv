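region,state,n
Anhui,normal,76426
Anhui,empty,32
Anhui,aeration,10
Anhui,new_grain,28
Anhui,condensation,7
Anhui,mildew,1
Fujian,normal,21682
Fujian,empty,95
Fujian,aeration,11
Fujian,new_grain,0
Fujian,condensation,7
Fujian,mildew,0
Jiangxi,normal,9692
Jiangxi,empty,5
Jiangxi,aeration,35
Jiangxi,new_grain,0
Jiangxi,condensation,9
Jiangxi,mildew,10
Henan,normal,6707
Henan,empty,34
Henan,aeration,0
Henan,new_grain,38
Henan,condensation,15
Henan,mildew,9
Hubei,normal,12901
Hubei,empty,39
Hubei,aeration,27
Hubei,new_grain,0
Hubei,condensation,5
Hubei,mildew,3
Hunan,normal,1947
Hunan,empty,41
Hunan,aeration,0
Hunan,new_grain,22
Hunan,condensation,5
Hunan,mildew,0
Guangdong,normal,7468
Guangdong,empty,16
Guangdong,aeration,12
Guangdong,new_grain,0
Guangdong,condensation,1
Guangdong,mildew,0
Guizhou,normal,8502
Guizhou,empty,39
Guizhou,aeration,5
Guizhou,new_grain,31
Guizhou,condensation,11
Guizhou,mildew,3
Shanxi,normal,11430
Shanxi,empty,42
Shanxi,aeration,17
Shanxi,new_grain,3
Shanxi,condensation,26
Shanxi,mildew,7
Gansu,normal,29022
Gansu,empty,51
Gansu,aeration,6
Gansu,new_grain,59
Gansu,condensation,14
Gansu,mildew,3
Jilin,normal,13758
Jilin,empty,92
Jilin,aeration,86
Jilin,new_grain,29
Jilin,condensation,5
Jilin,mildew,0
Xinjiang,normal,21725
Xinjiang,empty,51
Xinjiang,aeration,103
Xinjiang,new_grain,17
Xinjiang,condensation,16
Xinjiang,mildew,9
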
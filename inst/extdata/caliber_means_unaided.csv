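"vessel_class","cardiac_point","mean_um","sd_um"
"arteriole",1,90.6,10
"arteriole",2,91.2,9.8
"arteriole",3,90.4,10.3
"arteriole",4,91.3,9.4
"arteriole",5,90.8,9.1
"arteriole",6,90.5,8.7
"arteriole",7,90.1,9.7
"arteriole",8,90.8,9.9
"venule",1,111.9,12.6
"venule",2,111.4,11.7
"venule",3,111.6,13.1
"venule",4,113,13.2
"venule",5,112.1,12.9
"venule",6,113.3,12.5
"venule",7,112,14.3
"venule",8,112.3,13.6
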
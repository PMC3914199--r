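"vessel_class","cardiac_point","mean_um","sd_um"
"arteriole",1,99,9.5
"arteriole",2,101.5,10
"arteriole",3,98.2,9.6
"arteriole",4,98.6,9.7
"arteriole",5,98.2,9.8
"arteriole",6,99.3,11.1
"arteriole",7,100.4,9.7
"arteriole",8,100.6,8.4
"venule",1,109.4,14.5
"venule",2,108.6,15
"venule",3,113.3,16.1
"venule",4,114.3,14.5
"venule",5,113.6,17.3
"venule",6,115.2,15.7
"venule",7,110.9,16.1
"venule",8,112.7,17.2
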
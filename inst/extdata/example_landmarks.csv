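scapula_id,observer_id,measure_idx,landmark,x,y,z
S01,O1,1,AA,12.1,-45.3,1401.2
S01,O1,1,IA,18.6,-166.0,1462.9
S01,O1,1,TS,10.9,-44.8,1501.5
S01,O1,2,AA,12.4,-45.1,1401.0
S01,O1,2,IA,18.2,-165.7,1463.3
S01,O1,2,TS,11.2,-45.0,1501.2
S01,O2,1,AA,11.8,-45.6,1401.5
S01,O2,1,IA,18.9,-166.2,1462.6
S01,O2,1,TS,10.6,-44.5,1501.8
S01,O2,2,AA,12.0,-45.2,1401.3
S01,O2,2,IA,18.4,-165.9,1463.0
S01,O2,2,TS,11.0,-44.7,1501.4
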
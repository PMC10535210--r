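record_type,name,R1_rad,R2_rad,R3_rad,angular_velocity_rad_per_s
joint,HipL,,0.875,,
joint,KneeL,0.56,,,
joint,TibiaL,-0.015,-0.205,,
joint,HipR,,-0.345,,
joint,KneeR,1.37,,,
joint,ElbowL,,-1.045,,
joint,ElbowR,0.52,-0.965,,
joint,LumbarLow-LumbarUp,-0.785,0.305,,
joint,NeckLow-NeckUp,,-0.25,,
joint,ShoulderL,-1.61,0.15708,,
joint,ShoulderR,-1.645,-0.232,,
body_part,Lower left arm,,,,2.0305
body_part,Upper left arm,,,,2.2748
body_part,Lower right arm,,,,2.0295
body_part,Upper right arm,,,,2.2739
body_part,Left thigh,,,,2.0335
body_part,Left calf,,,,4.7907
body_part,Right thigh,,,,3.0025
body_part,Right calf,,,,1.2093
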
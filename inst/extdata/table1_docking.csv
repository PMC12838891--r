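compound,target,vina_kcal_mol,volume_A3
GLA,CK1D,-6.7,877
LIC,CK1D,-7.1,637
LID,CK1D,-8.0,637
MLT,CK1D,-6.8,877
GLA,PINK1,-7.1,2559
LIC,PINK1,-8.6,2559
LID,PINK1,-7.8,2559
MLT,PINK1,-6.9,2559
ICLID,CK1D,-8.5,637
IC261,CK1D,-6.5,637
ICLID,PINK1,-10.3,3727
IC261,PINK1,-7.3,2559
PFLID,CK1D,-9.8,637
PF670462,CK1D,-7.9,637
PFLID,PINK1,-10.0,3727
PF670462,PINK1,-7.8,2559
ICL,CK1D,-7.2,637
ICL,PINK1,-8.9,3727
PFL,CK1D,-10.8,651
PFL,PINK1,-11.2,3727
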
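residue_name,atom_name,charge,lj_rmin_half,lj_epsilon,gb_radius,gb_scale
*,N,-0.47,1.85,0.20,1.55,0.79
*,CA,0.07,2.275,0.02,1.70,0.72
*,C,0.51,2.00,0.11,1.70,0.72
*,O,-0.51,1.70,0.12,1.50,0.85
*,CB,0.00,2.175,0.055,1.70,0.72
*,H,0.31,0.2245,0.046,1.20,0.85
*,HA,0.09,1.32,0.022,1.20,0.85
*,OXT,-0.67,1.70,0.12,1.50,0.85
SER,OG,-0.66,1.77,0.1521,1.50,0.85
SER,HG,0.43,0.2245,0.046,1.20,0.85
THR,OG1,-0.66,1.77,0.1521,1.50,0.85
THR,HG1,0.43,0.2245,0.046,1.20,0.85
TYR,OH,-0.54,1.77,0.1521,1.50,0.85
TYR,HH,0.43,0.2245,0.046,1.20,0.85
ASP,CG,0.62,2.00,0.07,1.70,0.72
ASP,OD1,-0.76,1.70,0.12,1.50,0.85
ASP,OD2,-0.76,1.70,0.12,1.50,0.85
GLU,CG,-0.18,2.175,0.055,1.70,0.72
GLU,CD,0.62,2.00,0.07,1.70,0.72
GLU,OE1,-0.76,1.70,0.12,1.50,0.85
GLU,OE2,-0.76,1.70,0.12,1.50,0.85
ASN,CG,0.55,2.00,0.07,1.70,0.72
ASN,OD1,-0.55,1.70,0.12,1.50,0.85
ASN,ND2,-0.62,1.85,0.20,1.55,0.79
ASN,HD21,0.32,0.2245,0.046,1.20,0.85
ASN,HD22,0.30,0.2245,0.046,1.20,0.85
GLN,CG,-0.18,2.175,0.055,1.70,0.72
GLN,CD,0.55,2.00,0.07,1.70,0.72
GLN,OE1,-0.55,1.70,0.12,1.50,0.85
GLN,NE2,-0.62,1.85,0.20,1.55,0.79
GLN,HE21,0.32,0.2245,0.046,1.20,0.85
GLN,HE22,0.30,0.2245,0.046,1.20,0.85
LYS,CG,-0.18,2.175,0.055,1.70,0.72
LYS,CD,-0.18,2.175,0.055,1.70,0.72
LYS,CE,0.21,2.175,0.055,1.70,0.72
LYS,NZ,0.30,1.85,0.20,1.55,0.79
LYS,HZ1,0.33,0.2245,0.046,1.20,0.85
LYS,HZ2,0.33,0.2245,0.046,1.20,0.85
LYS,HZ3,0.33,0.2245,0.046,1.20,0.85
ARG,CG,-0.18,2.175,0.055,1.70,0.72
ARG,CD,0.20,2.175,0.055,1.70,0.72
ARG,NE,-0.70,1.85,0.20,1.55,0.79
ARG,HE,0.44,0.2245,0.046,1.20,0.85
ARG,CZ,0.64,2.00,0.07,1.70,0.72
ARG,NH1,-0.32,1.85,0.20,1.55,0.79
ARG,NH2,-0.32,1.85,0.20,1.55,0.79
HIS,ND1,-0.36,1.85,0.20,1.55,0.79
HIS,NE2,-0.36,1.85,0.20,1.55,0.79
TRP,NE1,-0.61,1.85,0.20,1.55,0.79
TRP,HE1,0.38,0.2245,0.046,1.20,0.85
CYS,SG,-0.23,2.00,0.45,1.80,0.96
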
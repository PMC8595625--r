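residue_i,residue_j,internal,vdw,electrostatic,polar_solv,nonpolar_solv,total
101,102,0,-0.42,-1.80,0.95,0,-1.27
101,103,0,-0.10,-3.20,1.60,0,-1.70
101,104,0,-0.05,0.40,-0.22,0,0.13
102,103,0,-0.55,-0.90,0.48,0,-0.97
102,104,0,-0.08,-0.30,0.17,0,-0.21
103,104,0,-0.60,-2.50,1.30,0,-1.80
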
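metal,rfd_oral,rfd_dermal,rfd_inhalation,kd,puf,kp,abs,vf
As,3.0e-4,3.0e-4,3.0e-4,620,0.0045,1e-3,0.03,
Hg,3.0e-4,2.1e-5,8.57e-5,120,0.0064,1e-3,0.001,32376.4
Cd,1.0e-3,2.5e-5,1.0e-3,320,0.36,1e-3,0.001,
Zn,0.3,0.3,0.3,134,0.11,1e-3,0.001,
Pb,3.5e-3,3.5e-3,3.5e-3,38000,0.012,1e-3,0.001,
Cu,0.04,0.04,0.04,2900,0.074,1e-3,0.001,
Cr,3.0e-3,7.5e-5,2.86e-5,2.0e5,0.010,1e-3,0.001,
Ni,0.02,8.0e-4,0.02,226,0.048,1e-3,0.001,
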
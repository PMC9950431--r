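aa,mw,charge,kd_hydro,top_idp,ss_potential
A,89.09,0,1.8,0.060,0
R,174.20,1,-4.5,0.180,0
N,132.12,0,-3.5,0.007,0
D,133.10,-1,-3.5,0.192,0
C,121.16,0,2.5,0.020,1
Q,146.15,0,-3.5,0.318,0
E,147.13,-1,-3.5,0.736,0
G,75.07,0,-0.4,0.102,0
H,155.16,0,-3.2,0.303,0
I,131.17,0,4.5,-0.486,0
L,131.17,0,3.8,-0.326,0
K,146.19,1,-3.9,0.586,0
M,149.21,0,1.9,-0.397,0
F,165.19,0,2.8,-0.697,0
P,115.13,0,-1.6,0.987,0
S,105.09,0,-0.8,0.341,0
T,119.12,0,-0.7,0.059,0
W,204.23,0,-0.9,-0.884,0
Y,181.19,0,-1.3,-0.510,0
V,117.15,0,4.2,-0.121,0
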
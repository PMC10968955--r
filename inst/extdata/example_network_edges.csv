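node,ES,D,ANX,M,ADHD,PLEs,OCD,Age,Ed,G,Emp
ES,0,0,0,0.072,0.062,0.113,0,0,0.057,0.177,0
D,0,0,0.590,0,0.191,0.046,0.077,0,0,0,0
ANX,0,0.590,0,0,0.175,0,0.061,0,0,0,0
M,0.072,0,0,0,0.128,0.279,0,0.065,0,0,0
ADHD,0.062,0.191,0.175,0.128,0,0.027,0.246,0,0,0,0
PLEs,0.113,0.046,0,0.279,0.027,0,0.398,0,0,0,0
OCD,0,0.077,0.061,0,0.246,0.398,0,0,0,0.082,0
Age,0,0,0,0.065,0,0,0,0,0.304,0.052,0
Ed,0.057,0,0,0,0,0,0,0.304,0,0,0.445
G,0.177,0,0,0,0,0,0.082,0.052,0,0,0.355
Emp,0,0,0,0,0,0,0,0,0.445,0.355,0
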
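# Baseline parameterisation of the tripartite CMC construction game:
# lead hospital, primary healthcare institutions, government departments.
I = 26
U = 5
Sl = 14
Tp = 12
R = 3
Sp = 2
D = 25
v = 0.5
pi = 0.5
eps = 0.5
xi = 0.5
Tg = 6
F = 6
A = 10
phi = 0.5
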
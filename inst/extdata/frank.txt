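species A init=1 exchanged inflow=1
species L init=0.10000000000000001 exchanged inflow=0
species D init=0.10000000000000001 exchanged inflow=0
species P init=0 exchanged inflow=0
reaction PL: A <-> L ; kf=0.10000000000000001, kr=0.005000000000000001
reaction PD: A <-> D ; kf=0.10000000000000001, kr=0.005000000000000001
reaction AL: A + L <-> 2 L ; kf=1, kr=0.050000000000000003
reaction AD: A + D <-> 2 D ; kf=1, kr=0.050000000000000003
reaction IN: L + D <-> P ; kf=1, kr=0.050000000000000003
system T=300 flow=0.10000000000000001
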
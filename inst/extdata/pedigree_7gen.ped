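# Synthetic 26-member, 7-generation pedigree (10 founders).
# Columns: family id father mother sex (1=male, 2=female); 0 = founder.
FAM1 A1 0 0 1
FAM1 A2 0 0 2
FAM1 B1 A1 A2 1
FAM1 B2 A1 A2 1
FAM1 B3 A1 A2 2
FAM1 C1 0 0 2
FAM1 C2 0 0 2
FAM1 D1 B1 C1 1
FAM1 D2 B1 C1 2
FAM1 D3 B2 C2 1
FAM1 D4 B2 C2 2
FAM1 E1 0 0 2
FAM1 E2 0 0 2
FAM1 F1 D1 E1 1
FAM1 F2 D1 E1 2
FAM1 F3 D3 E2 1
FAM1 G1 0 0 2
FAM1 G2 0 0 2
FAM1 H1 F1 G1 1
FAM1 H2 F1 G1 2
FAM1 H3 F3 G2 1
FAM1 I1 0 0 2
FAM1 J1 H1 I1 1
FAM1 J2 H1 I1 2
FAM1 K1 0 0 2
FAM1 L1 J1 K1 1
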
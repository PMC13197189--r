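# [15N,13C2]acetonitrile SABRE model: CH3-13C#15N substrate (6 spins),
# complex = substrate + 2 Ir hydrides (8 spins).
#
# Parameter provenance: 1J(CH) = 136 Hz and 1J(CN) = -18 Hz are the
# values quoted for this isotopologue; 1J(CC) = 56 Hz and
# 2J(CH) = -5.2 Hz are recovered from the quoted first-order line
# positions (5/8 JCC + 3 x 2JCH = 19.4 Hz, 3/4 JCC + 2JCH = 36.8 Hz);
# the remaining couplings are standard literature values for
# acetonitrile (2JNC ~ 3 Hz, 3JNH ~ -1.7 Hz). Hydride parameters are
# typical of Ir-IMes SABRE complexes with N-bound substrates
# (J(HH') ~ -7 Hz, trans J(15N-H) ~ -24 Hz); cis couplings are set to
# zero. T1 times are synthetic but typical: tens of seconds for the free
# substrate at microtesla fields, a few seconds in the complex.
substrate:
  nuclei:
    - {label: N1, isotope: 15N, t1_s: 20}
    - {label: C2, isotope: 13C, t1_s: 12}
    - {label: C3, isotope: 13C, t1_s: 10}
    - {label: H1, isotope: 1H, t1_s: 5}
    - {label: H2, isotope: 1H, t1_s: 5}
    - {label: H3, isotope: 1H, t1_s: 5}
  j_hz:
    - [N1, C2, -18.0]
    - [N1, C3, 3.0]
    - [C2, C3, 56.0]
    - [C3, H1, 136.0]
    - [C3, H2, 136.0]
    - [C3, H3, 136.0]
    - [C2, H1, -5.2]
    - [C2, H2, -5.2]
    - [C2, H3, -5.2]
    - [N1, H1, -1.7]
    - [N1, H2, -1.7]
    - [N1, H3, -1.7]
  groups:
    - {name: CH3, members: [H1, H2, H3]}
complex:
  hydrides:
    - {label: Ha, isotope: 1H, t1_s: 1.5}
    - {label: Hb, isotope: 1H, t1_s: 1.5}
  j_hz:
    - [Ha, Hb, -7.0]
    - [N1, Ha, -24.0]
    - [C2, Ha, -1.0]
  t1_s: {N1: 5, C2: 4, C3: 4, H1: 2, H2: 2, H3: 2}
kinetics: {kd_s1: 10, cs: 0.1}
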
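# [15N,13C4]butyronitrile SABRE model: CH3-CH2-CH2-13C#15N substrate
# (12 spins: 15N, 4 x 13C, 7 protons in two CH2 groups and one CH3
# group); complex = substrate + 2 hydrides (14 spins).
#
# Parameter provenance: 1J(CH) = 136 Hz for the proton-bearing carbons
# (the CH2 and CH3 fingerprints sit at 3/2 x and 2 x this coupling) and
# 1J(CN) = -18 Hz are quoted for the nitrile moiety; the remaining
# couplings are standard aliphatic-nitrile literature values. Hydride
# parameters as in the acetonitrile model. T1 values are synthetic but
# typical.
substrate:
  nuclei:
    - {label: N1, isotope: 15N, t1_s: 20}
    - {label: C2, isotope: 13C, t1_s: 12}
    - {label: C3, isotope: 13C, t1_s: 10}
    - {label: C4, isotope: 13C, t1_s: 10}
    - {label: C5, isotope: 13C, t1_s: 10}
    - {label: H31, isotope: 1H, t1_s: 5}
    - {label: H32, isotope: 1H, t1_s: 5}
    - {label: H41, isotope: 1H, t1_s: 5}
    - {label: H42, isotope: 1H, t1_s: 5}
    - {label: H51, isotope: 1H, t1_s: 5}
    - {label: H52, isotope: 1H, t1_s: 5}
    - {label: H53, isotope: 1H, t1_s: 5}
  j_hz:
    - [N1, C2, -18.0]
    - [N1, C3, 3.0]
    - [C2, C3, 55.0]
    - [C3, C4, 35.0]
    - [C4, C5, 35.0]
    - [C3, H31, 136.0]
    - [C3, H32, 136.0]
    - [C4, H41, 136.0]
    - [C4, H42, 136.0]
    - [C5, H51, 136.0]
    - [C5, H52, 136.0]
    - [C5, H53, 136.0]
    - [C2, H31, -10.0]
    - [C2, H32, -10.0]
    - [C3, H41, -4.5]
    - [C3, H42, -4.5]
    - [C4, H31, -4.5]
    - [C4, H32, -4.5]
    - [C4, H51, -4.5]
    - [C4, H52, -4.5]
    - [C4, H53, -4.5]
    - [C5, H41, -4.5]
    - [C5, H42, -4.5]
    - [N1, H31, -1.7]
    - [N1, H32, -1.7]
    - [H31, H41, 7.0]
    - [H31, H42, 7.0]
    - [H32, H41, 7.0]
    - [H32, H42, 7.0]
    - [H41, H51, 7.0]
    - [H41, H52, 7.0]
    - [H41, H53, 7.0]
    - [H42, H51, 7.0]
    - [H42, H52, 7.0]
    - [H42, H53, 7.0]
  groups:
    - {name: K1, members: [H31, H32]}
    - {name: K2, members: [H41, H42]}
    - {name: K3, members: [H51, H52, H53]}
complex:
  hydrides:
    - {label: Ha, isotope: 1H, t1_s: 1.5}
    - {label: Hb, isotope: 1H, t1_s: 1.5}
  j_hz:
    - [Ha, Hb, -7.0]
    - [N1, Ha, -24.0]
    - [C2, Ha, -1.0]
  t1_s: {N1: 5, C2: 4, C3: 4, C4: 4, C5: 4,
         H31: 2, H32: 2, H41: 2, H42: 2, H51: 2, H52: 2, H53: 2}
kinetics: {kd_s1: 50, cs: 0.37}
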
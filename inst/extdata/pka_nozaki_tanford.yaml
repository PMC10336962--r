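# Intrinsic pKa values (Nozaki-Tanford) used for fixed-charge assignment.
# type: acid -> deprotonated form carries -1; base -> protonated form carries +1
residues:
  D: {pka: 4.0, type: acid}
  E: {pka: 4.4, type: acid}
  H: {pka: 6.3, type: base}
  C: {pka: 9.5, type: acid}
  "Y": {pka: 9.6, type: acid}
  K: {pka: 10.4, type: base}
  R: {pka: 12.0, type: base}
termini:
  n_terminus: {pka: 7.5, type: base}
  c_terminus: {pka: 3.8, type: acid}
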
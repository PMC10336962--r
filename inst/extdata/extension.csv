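name,n_residues,rg_exp,rg_exp_err,rg_scaling,rg_bead_necklace,rg_martini,comment
KEIF,NA,17.6,NA,16.8,16.0,16.0,Short peptide extension set; atomistic reference 16.4
Hst5_dimer,48,18.7,NA,NA,21.0,23.6,(Histatin 5)2; atomistic reference 23.3
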
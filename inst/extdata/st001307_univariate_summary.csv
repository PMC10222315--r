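metabolite,fc,log2_fc,neg_log10_p,p_adj,regulation
Succinic acid,2.04,1.03,4.35,8.64e-4,UP
Aminoisobutyric acid,0.60,0.73,4.35,4.95e-4,DOWN
Butyric acid,0.18,-2.43,4.17,4.60e-4,DOWN
Isoleucine,1.63,0.70,4.03,4.60e-4,UP
Leucine,1.73,0.79,3.52,8.19e-4,UP
Oxalic acid,,,1.55,0.07,
Alanine,,,1.02,0.20,
Ethanolamine,,,0.97,0.20,
Caproic acid,,,0.62,0.39,
Oleic acid,,,0.58,0.39,
Lysine,,,0.39,0.55,
Phenol,,,0.33,0.58,
2-Furoic acid,,,0.12,0.86,
Palmitic acid,,,0.09,0.86,
Tyramine,,,0.04,0.91,
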
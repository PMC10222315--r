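metabolite,cutoff,auc,ci_low,ci_high,sensitivity,specificity
Aminoisobutyric acid,-0.103,0.806,0.700,0.897,0.675,0.805
Succinic acid,-0.121,0.797,0.683,0.894,0.750,0.770
Butyric acid,-0.254,0.790,0.675,0.883,0.750,0.694
Isoleucine,-0.078,0.783,0.679,0.875,0.750,0.666
Leucine,-0.104,0.765,0.646,0.861,0.820,0.638
Oxalic acid,-0.171,0.675,0.552,0.805,0.675,0.611
Ethanolamine,-0.149,0.609,0.492,0.734,0.550,0.666
Alanine,-1.130,0.601,0.471,0.725,0.425,0.805
Caproic acid,-0.089,0.588,0.465,0.705,0.550,0.583
Oleic acid,0.003,0.587,0.448,0.720,0.500,0.722
Lysine,-0.225,0.556,0.435,0.687,0.600,0.611
2-Furoic acid,-0.207,0.551,0.412,0.673,0.650,0.472
Palmitic acid,-4.170,0.544,0.413,0.682,0.675,0.472
Tyramine,-0.220,0.514,0.384,0.640,0.525,0.527
Phenol,-0.465,0.514,0.377,0.640,0.475,0.583
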
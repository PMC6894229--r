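metabolite,p_value_printed,fold_change,p_er_printed,fold_change_er
3-Hydroxybutyrate,0.010,-1.06,0.010,-1.07
Acetate,<0.001,-1.22,<0.001,-1.21
Acetoacetate,<0.001,-1.25,<0.001,-1.20
Acetone,0.250,-1.18,0.508,-1.11
Alanine,0.692,1.01,0.544,-1.02
Asparagine,0.237,-1.05,0.376,-1.04
Citrate,0.503,1.03,0.726,1.01
Creatine,0.905,-1.01,0.704,-1.02
Creatinine,0.066,-1.06,0.039,-1.07
Dimethylsulfone,0.319,-1.09,0.154,-1.15
Glucose,0.969,1.00,0.972,1.00
Glutamine,0.005,-1.06,0.013,-1.07
Glycerol,0.065,-1.05,0.054,-1.06
Glycoprotein,0.243,-1.06,0.408,-1.05
Isoleucine,<0.001,-1.26,0.001,-1.22
Isopropyl alcohol,0.009,-1.12,0.038,-1.10
Lactate,<0.001,1.36,<0.001,1.26
Leucine,<0.001,-1.20,0.002,-1.17
Lysine,<0.001,-1.12,<0.001,-1.11
Methanol,0.495,-1.04,0.511,-1.04
Methionine,0.052,-1.11,0.062,-1.11
N-acetylated groups,<0.001,-1.15,<0.001,-1.15
Phenylalanine,<0.001,-1.12,<0.001,-1.13
Proline,0.298,-1.03,0.236,-1.03
Propylene Glycol,<0.001,-1.13,0.004,-1.10
Pyruvate,<0.001,1.27,<0.001,1.23
Threonine,0.035,-1.07,0.016,-1.08
Valine,<0.001,-1.31,<0.001,-1.29
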
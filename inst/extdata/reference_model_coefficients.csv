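descriptor,beta,se,z,odds_ratio,ci_lower,ci_upper
s_phobic_avg,-0.807,0.045,-17.913,0.446,0.408,0.487
s_pos_area,0.617,0.051,12.016,1.853,1.675,2.049
s_neg_area,0.622,0.047,13.112,1.862,1.697,2.043
norm_s_b,-0.408,0.029,-13.972,0.665,0.628,0.704
s_bs,-0.286,0.036,-7.992,0.751,0.700,0.806
s_do,-0.138,0.050,-2.738,0.872,0.790,0.962
fd,-0.265,0.024,-11.211,0.767,0.733,0.804
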
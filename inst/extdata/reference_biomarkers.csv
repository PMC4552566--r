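metabolite,mfc,log2_mfc,p_adj,neglog10_p
Acetylcarnitine (C2),1.97,0.98,2.84E-13,12.55
Propionylcarnitine (C3),1.52,0.6,2.84E-13,12.55
Alanine,1.42,0.51,2.84E-13,12.55
Valerylcarnitine (C5),1.38,0.46,4.49E-09,8.35
Arginine,1.36,0.44,6.85E-06,5.16
Glucose,1.32,0.4,2.38E-08,7.62
Butyrylcarnitine (C4),1.27,0.35,4.31E-08,7.37
Methylmalonylcarnitine (C3-DC-M),1.26,0.33,6.93E-08,7.16
Hydroxyvalerylcarnitine (C5-OH),1.26,0.33,3.35E-05,4.48
Octadecadienylcarnitine (C18:2),1.21,0.28,1.05E-04,3.98
Ornithine,1.19,0.25,1.87E-05,4.73
Tryptophan,1.18,0.24,9.28E-03,2.03
Octadecanoylcarnitine (C18),1.17,0.23,1.97E-05,4.71
Methionine,1.16,0.21,9.81E-03,2.01
Histidine,1.14,0.18,1.72E-05,4.76
Phenylalanine,1.14,0.18,1.51E-06,5.82
Hexadecanoylcarnitine (C16),1.12,0.16,7.68E-03,2.11
Citrulline,1.12,0.16,9.91E-02,1.00
Glutamic_Acid,1.12,0.17,1.48E-09,8.83
Tyrosine,1.12,0.17,1.21E-07,6.92
Glycine,1.11,0.15,1.48E-09,8.83
Lysine,1.11,0.15,7.77E-03,2.11
Proline,1.11,0.16,2.09E-02,1.68
Serine,1.11,0.15,9.10E-03,2.04
Octadecenoylcarnitine (C18:1),1.10,0.14,1.04E-02,1.98
Threonine,1.09,0.12,2.25E-02,1.65
Valine,1.09,0.12,2.25E-02,1.65
xLeucine (Leucine + Isoleucine),1.09,0.12,1.08E-02,1.97
Carnitine (C0),0.92,-0.12,1.08E-02,1.97
Aspartic_Acid,0.88,-0.19,4.55E-01,0.34
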
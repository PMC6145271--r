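{"k1":0.33,"k2":0.061,"k3":0.142,"k4":3.7e-05,"k5":1.517e-05,"k6":0.414,"k7":0.064,"k8":0.013,"k9":0.001458,"k10":0.009855,"k11":0.101,"k12":0.0017,"cor_bio":1.118,"cor_NPN":0.832,"cor_X":0.025,"y1_max":0.2,"y4_max":1.5,"y5_max":0.2,"N_bio":0.2,"MW_bio":24.63,"N_NPN":1,"MW_NPN":120,"AW_N":14.007}
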
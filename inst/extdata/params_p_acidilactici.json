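{"k1":0.244,"k2":0.088,"k3":0.141,"k4":0.000464,"k5":1.275e-05,"k6":0.001112,"k7":0.095,"k8":0.0002623,"k9":0.0017498,"k10":0.006674,"k11":1.28,"k12":0.0019,"cor_bio":1.094,"cor_NPN":0.723,"cor_X":0.046,"y1_max":0.3,"y4_max":1.5,"y5_max":0.2,"N_bio":0.2,"MW_bio":24.63,"N_NPN":1,"MW_NPN":120,"AW_N":14.007}
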
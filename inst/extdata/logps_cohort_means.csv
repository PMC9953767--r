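lobe,band,mean_left,sem_left,mean_right,sem_right,p,test
F,delta,1.24,0.05,1.26,0.06,0.379,paired t
F,theta,0.72,0.05,0.72,0.04,0.854,paired t
F,alpha,0.90,0.06,0.91,0.06,0.424,wilcoxon signed-rank
F,beta,0.85,0.05,0.89,0.05,0.068,paired t
PO,delta,1.18,0.05,1.19,0.05,0.456,paired t
PO,theta,0.85,0.06,0.85,0.06,0.556,paired t
PO,alpha,1.52,0.10,1.53,0.10,0.400,paired t
PO,beta,1.02,0.05,0.99,0.05,0.291,wilcoxon signed-rank
T,delta,1.31,0.06,1.33,0.06,0.490,paired t
T,theta,0.84,0.06,0.80,0.06,0.084,paired t
T,alpha,1.28,0.08,1.27,0.09,0.526,wilcoxon signed-rank
T,beta,1.07,0.05,1.02,0.05,0.161,paired t
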
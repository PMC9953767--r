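lobe,age_group,hemisphere,band,mean,sem
F,<20,left,delta,1.64,0.11
F,<20,left,alpha,1.21,0.07
F,<20,left,theta,1.10,0.05
F,<20,left,beta,0.90,0.03
F,<20,right,delta,1.67,0.13
F,<20,right,alpha,1.30,0.12
F,<20,right,theta,1.09,0.09
F,<20,right,beta,0.98,0.05
F,20-50,left,delta,1.16,0.05
F,20-50,left,beta,0.81,0.07
F,20-50,left,alpha,0.77,0.07
F,20-50,left,theta,0.60,0.03
F,20-50,right,delta,1.18,0.06
F,20-50,right,beta,0.86,0.06
F,20-50,right,alpha,0.77,0.06
F,20-50,right,theta,0.63,0.04
F,>50,left,delta,1.11,0.11
F,>50,left,alpha,1.09,0.11
F,>50,left,beta,0.96,0.11
F,>50,left,theta,0.78,0.18
F,>50,right,delta,1.08,0.05
F,>50,right,alpha,1.06,0.14
F,>50,right,beta,0.90,0.09
F,>50,right,theta,0.68,0.12
PO,<20,left,alpha,2.07,0.11
PO,<20,left,delta,1.57,0.09
PO,<20,left,theta,1.28,0.12
PO,<20,left,beta,1.12,0.07
PO,<20,right,alpha,2.15,0.10
PO,<20,right,delta,1.56,0.09
PO,<20,right,theta,1.27,0.11
PO,<20,right,beta,1.14,0.07
PO,20-50,left,alpha,1.35,0.12
PO,20-50,left,delta,1.10,0.05
PO,20-50,left,beta,0.98,0.07
PO,20-50,left,theta,0.73,0.06
PO,20-50,right,alpha,1.35,0.11
PO,20-50,right,delta,1.11,0.05
PO,20-50,right,beta,0.95,0.07
PO,20-50,right,theta,0.72,0.06
PO,>50,left,alpha,1.57,0.22
PO,>50,left,beta,1.13,0.09
PO,>50,left,delta,1.00,0.11
PO,>50,left,theta,0.87,0.04
PO,>50,right,alpha,1.58,0.25
PO,>50,right,beta,1.00,0.15
PO,>50,right,delta,1.05,0.09
PO,>50,right,theta,0.88,0.05
T,<20,left,alpha,1.79,0.07
T,<20,left,delta,1.71,0.07
T,<20,left,beta,1.27,0.05
T,<20,left,theta,1.27,0.10
T,<20,right,alpha,1.93,0.14
T,<20,right,delta,1.83,0.06
T,<20,right,beta,1.24,0.08
T,<20,right,theta,1.28,0.12
T,20-50,left,delta,1.20,0.05
T,20-50,left,alpha,1.11,0.09
T,20-50,left,beta,1.00,0.06
T,20-50,left,theta,0.71,0.05
T,20-50,right,delta,1.21,0.06
T,20-50,right,alpha,1.06,0.09
T,20-50,right,beta,0.96,0.07
T,20-50,right,theta,0.66,0.06
T,>50,left,alpha,1.41,0.14
T,>50,left,delta,1.29,0.19
T,>50,left,beta,1.15,0.11
T,>50,left,theta,0.87,0.12
T,>50,right,alpha,1.36,0.12
T,>50,right,delta,1.22,0.23
T,>50,right,beta,0.95,0.10
T,>50,right,theta,0.83,0.15
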
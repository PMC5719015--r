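term,estimate,std_error,z_value,p_value
beta0,-3.50,0.09,-39.57,2.0e-16
beta1,0.26,0.10,2.56,0.0103
gamma1,-5.35,1.06,-5.04,4.74e-07
beta2,1.59,0.07,22.40,2.0e-16
gamma2,-0.03,0.01,-2.65,0.0081
beta2:directionN,-0.25,0.12,-2.19,0.0281
beta2:directionNE,-0.59,0.09,-6.10,1.04e-09
beta2:directionNW,1.04,0.10,10.20,2.0e-16
beta2:directionS,0.09,0.11,0.78,0.4343
beta2:directionSE,-0.12,0.12,-0.98,0.3260
beta2:directionSW,1.21,0.10,11.52,2.0e-16
beta2:directionW,-0.17,0.08,-2.18,0.0293
gamma2:directionN,-0.02,0.02,-0.69,0.4877
gamma2:directionNE,0.24,0.04,6.18,6.35e-10
gamma2:directionNW,-0.52,0.06,-9.19,2.0e-16
gamma2:directionS,-0.02,0.02,-0.80,0.4235
gamma2:directionSE,-0.02,0.02,-1.25,0.2080
gamma2:directionSW,-0.05,0.03,-1.66,0.0955
gamma2:directionW,0.02,0.01,2.09,0.0361
beta2:year2015,-0.23,0.04,-6.10,1.04e-09
gamma2:year2015,-0.02,0.01,-2.41,0.0156
beta2:directionN:year2015,-0.04,0.06,-0.66,0.5074
beta2:directionNE:year2015,0.31,0.05,5.45,5.04e-08
beta2:directionNW:year2015,-0.78,0.06,-12.81,2.0e-16
beta2:directionS:year2015,-0.23,0.06,-3.66,0.0002
beta2:directionSE:year2015,-0.02,0.06,-0.31,0.7520
beta2:directionSW:year2015,-0.94,0.07,-13.12,2.0e-16
beta2:directionW:year2015,0.12,0.04,2.89,0.0038
gamma2:directionN:year2015,0.03,0.00,3.32,0.0008
gamma2:directionNE:year2015,-0.23,0.03,-6.29,3.13e-10
gamma2:directionNW:year2015,0.27,0.03,9.44,2.0e-16
gamma2:directionS:year2015,0.02,0.01,1.68,0.0912
gamma2:directionSE:year2015,0.02,0.01,2.07,0.0383
gamma2:directionSW:year2015,0.01,0.02,0.53,0.5926
gamma2:directionW:year2015,-0.01,0.00,-0.49,0.6238
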
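group,acaricide,target,method,n,slope,slope_se,chi2,df,ld50,ld50_lo,ld50_hi,ld90,ld90_lo,ld90_hi,dd,dose_unit
1A1,fenothiocarb,nerve system,RCV,235,1.7,0.2,16.2,13,0.252,0.192,0.334,1.41,0.939,2.492,2.8,ug/cm2
1B,monocrotophos,nerve system,RCV,182,2.1,0.3,25.5,10,0.055,0.034,0.097,0.22,0.118,0.894,0.441,ug/cm2
1B,omethoate,nerve system,RCV,141,1.1,0.3,6.4,7,0.008,0.005,0.014,0.11,0.04,1.575,0.219,ug/cm2
2A,endosulfan,nerve system,RCV,232,1.4,0.2,23.8,13,0.162,0.097,0.261,1.32,0.697,4.056,2.6,ug/cm2
3A,bifenthrin,nerve system,RCV,286,1.7,0.2,18.5,16,0.027,0.021,0.035,0.16,0.107,0.255,0.31,ug/cm2
6,abamectin,nerve system,RCV,189,1.6,0.2,20.1,10,0.002,0.001,0.003,0.01,0.006,0.058,0.023,ug/cm2
10B,etoxazole_rcv,metabolic pathway,RCV,204,0.9,0.4,5.4,10,246.3,24,nd,7912,150.2,nd,15824,ug/cm2
10B,etoxazole,metabolic pathway,leaf_dip,625,3.3,0.3,5.3,3,0.0083,0.007,0.011,0.021,0.015,0.033,0.041,ppm
12B,fenbutatin oxide,metabolic pathway,RCV,204,2.4,0.3,9.4,10,2.0,1.6,2.6,7.03,5.061,11.494,14.1,ug/cm2
13,chlorfenapyr,metabolic pathway,RCV,228,2.6,0.3,18.4,13,0.002,0.0016,0.003,0.01,0.005,0.013,0.014,ug/cm2
15,flufenoxuron,metabolic pathway,RCV,204,nd,nd,nd,nd,nd,nd,nd,nd,nd,nd,nd,ug/cm2
19,amitraz,nerve system,RCV,199,2.0,0.2,6.3,10,0.39,0.303,0.501,1.7,1.2,2.9,3.4,ug/cm2
21A,pyridaben,metabolic pathway,RCV,165,0.9,0.1,8.7,11,1,0.6,1.6,28.7,12.8,114.6,57.4,ug/cm2
21A,tebufenpyrad,metabolic pathway,RCV,287,1.4,0.1,8.6,16,0.054,0.039,0.073,0.47,0.303,0.846,0.933,ug/cm2
23,spiromesifen,metabolic pathway,RCV,204,1.8,0.2,5.3,10,1.5,1.2,2,7.93,5.2,15.0,15.9,ug/cm2
25,cyenopyrafen,metabolic pathway,RCV,193,2.1,0.3,12.9,10,0.025,0.019,0.032,0.1,0.07,0.161,0.197,ug/cm2
25,cyflumetofen,metabolic pathway,RCV,244,2.9,0.3,12.3,12,0.112,0.094,0.133,0.31,0.245,0.428,0.618,ug/cm2
UN,bifenazate,unknown,RCV,238,2.9,0.3,2.3,13,0.083,0.07,0.098,0.23,0.185,0.321,0.464,ug/cm2
UN,dicofol,unknown,RCV,185,1.0,0.2,11.3,10,0.9,0.6,1.8,16.6,5.7,156.7,33.3,ug/cm2
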
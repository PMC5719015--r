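year,distance_m,n_screened,n_resistant,frequency_printed,power_printed
2014,0.5,2591,1546,0.60,>0.95
2014,1,2157,1154,0.54,>0.95
2014,2,3201,1281,0.40,>0.95
2014,4,2456,781,0.32,>0.95
2014,10,2325,498,0.21,>0.95
2014,15,2182,282,0.13,0.88
2014,25,3385,315,0.09,0.95
2014,35,5585,519,0.09,0.95
2014,50,23820,941,0.04,0.90
2015,0.1,5198,2218,0.43,>0.95
2015,0.5,5941,1645,0.28,>0.95
2015,1,5247,1120,0.21,>0.95
2015,2,6696,1535,0.23,>0.95
2015,4,6376,1488,0.23,>0.95
2015,10,2003,247,0.12,>0.95
2015,15,4782,437,0.10,0.88
2015,25,3661,278,0.08,0.95
2015,35,3285,202,0.06,0.80
2015,50,10047,326,0.03,0.92
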
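label,row,arc,height_mean,height_sd,bt_mean,bt_sd,bb_mean,bb_sd,area_mean,area_sd,barrel_volume_mean,barrel_volume_sd,column_height_mean,column_height_sd,column_diameter_mean,column_diameter_sd,column_volume_mean,column_volume_sd,orientation_mean,orientation_sd
A1,0,1,322,34,455,32,777,50,85500,16000,0.028,0.007,1651,126,330,31,0.14,0.03,8.3,4.1
A2,0,2,337,45,467,52,805,55,83000,14600,0.028,0.006,1759,113,325,29,0.15,0.02,12.9,4.8
A3,0,3,315,29,485,35,800,34,64800,10700,0.020,0.004,1825,98,287,24,0.12,0.02,15.5,4.4
A4,0,4,316,39,489,38,805,37,65000,15000,0.021,0.006,1916,94,288,33,0.12,0.03,16.9,4.5
alpha,0.5,0,308,39,479,53,788,48,87900,25000,0.028,0.010,1600,118,335,48,0.14,0.04,5.5,3.4
B1,1,1,346,34,481,48,827,56,87400,15900,0.030,0.006,1736,92,334,30,0.15,0.03,4.4,3.5
B2,1,2,344,27,490,45,834,47,90100,14800,0.031,0.005,1815,93,339,28,0.16,0.03,7.2,4.3
B3,1,3,354,29,490,53,844,57,76600,10700,0.027,0.004,1899,98,312,22,0.15,0.02,10.3,5.1
B4,1,4,352,21,501,52,853,52,78900,11500,0.028,0.005,1961,93,317,23,0.15,0.02,14.7,4.3
beta,1.5,0,338,43,472,45,810,47,101800,16600,0.035,0.008,1623,103,360,29,0.16,0.03,6.7,2.7
C1,2,1,358,24,478,58,836,65,100800,17300,0.036,0.007,1800,110,358,31,0.18,0.03,6.1,4.6
C2,2,2,360,24,496,43,856,37,103000,13700,0.037,0.005,1892,100,362,24,0.20,0.03,0,0
C3,2,3,354,31,534,61,889,56,104400,20500,0.037,0.007,1985,100,365,36,0.21,0.04,7.3,5.1
C4,2,4,363,47,557,80,920,70,90300,22500,0.033,0.011,2038,94,339,42,0.18,0.05,10.3,5.2
gamma,2.5,0,355,31,478,48,833,48,127300,27200,0.045,0.009,1713,132,403,43,0.22,0.04,11.1,5.6
D1,3,1,371,33,491,45,863,55,111700,15200,0.042,0.007,1865,104,377,26,0.21,0.03,7.8,4.4
D2,3,2,362,39,526,61,888,56,124200,16100,0.045,0.008,1957,101,398,26,0.24,0.04,5.1,4.5
D3,3,3,368,23,552,60,920,60,116400,19700,0.043,0.008,2046,87,385,33,0.24,0.04,3.2,2.4
D4,3,4,363,46,556,57,919,54,103400,7500,0.038,0.005,2081,98,363,13,0.22,0.02,5.9,3.2
delta,3.5,0,354,27,506,48,860,52,143100,32700,0.051,0.012,1845,95,427,49,0.26,0.06,12.4,4.5
E1,4,1,343,28,546,45,888,60,145600,20500,0.050,0.008,1977,77,431,30,0.29,0.04,9.4,5.1
E2,4,2,355,30,557,54,912,60,158900,16100,0.056,0.007,2096,58,450,23,0.33,0.04,7.6,5.1
E3,4,3,364,38,549,58,912,71,157800,23200,0.057,0.007,2117,84,448,33,0.33,0.05,6.5,3.6
E4,4,4,344,48,580,48,924,45,123000,20000,0.042,0.010,2111,91,396,32,0.26,0.04,5.9,2.9
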
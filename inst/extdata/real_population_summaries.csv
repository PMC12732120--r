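population,stratum,N,m,n,Xmin,Xmax,Mx,My,sigma_x,fx,fy,rho,TM,DM,Sk,QA,QD,MAD,QR,MR
Population-1,1,36,18,9,388,1534,1016.500,116230,402.609,0.000951993,0.00000835,0.084,891.188,982.650,1.008,891.875,982.650,289,378.250,961
Population-1,2,36,18,9,84,478,206,49661,424.937,0.004094403,0.0000143374,0.875,210.688,231,1.023,215.375,62.875,267,125.750,281
Population-2,1,36,18,9,24,1986,168.500,10484.500,438.519,0.002463666,0.00004033736,0.912,193.438,432.500,2.106,218.375,127.125,193.438,252.25,1005
Population-2,2,36,18,9,24,2055,171.500,10494.500,452.713,0.002315051,0.00004086913,0.5194465,195.750,431.500,2.345,220,132.500,99,265,1039.500
Population-3,1,36,18,9,28,95,60.664,52.728,10.130,0.0004729,0.0000219,0.337,61.623,61.600,0.300,54.287,6.840,8.100,13.721,61.500
Population-3,2,36,18,9,15,75,44.205,46.339,12.750,0.0003791,0.0000481,0.496,45.287,45.242,0.500,48.940,8.614,10.200,17.201,45
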
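gsp,description,units,family,p1,p2,p3,left_kind,left,right_kind,right,integer
B01ND,Thermal time from planting to first branching,Cd,triangular,189,1447,764,,,,,0
B12ND,Mean thermal time between branching levels after first branching,Cd,triangular,284,899,456,,,,,0
LAXS,Maximum individual leaf area,cm2,lognormal,5.748,0.314,,probability,0.001,probability,0.9,0
SLAS,Specific leaf area,cm2/g,normal,242.613,59.975,,probability,0.1,probability,0.9,0
LLIFA,Active leaf area duration in thermal time after full expansion,Cd,weibull,4.183,1015.34,,value,100,probability,0.9,0
LPEFR,Leaf-petiole weight fraction,-,gamma,8.984,0.0237,,value,0.1,probability,0.9,0
LNSLP,Leaf appearance slope as proportion of the reference curve,-,uniform,0.7,1.3,,,,,,0
NODWT,Individual node weight,g,weibull,3.157,9.253,,value,1,probability,0.9,0
NODL,Internode length,cm,lognormal,0.502,0.398,,probability,0.001,probability,0.9,0
PARUE,Radiation use efficiency,g/MJ,lognormal,0.337,0.310,,probability,0.1,probability,0.9,0
TBLSZ,Base temperature for leaf development,C,uniform,11,17,,,,,,0
BR1F,Branch number per fork at fork 1,#,uniform,1,4,,,,,,1
BR2F,Branch number per fork at fork 2,#,uniform,1,4,,,,,,1
BR3F,Branch number per fork at fork 3,#,uniform,1,4,,,,,,1
BR4F,Branch number per fork at fork 4,#,uniform,1,4,,,,,,1
KCAN,Photosynthetically active radiation extinction parameter,-,uniform,0.58,1.01,,,,,,0
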
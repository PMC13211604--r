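name,category,mw,lifetime,odp,gwp100,mdl,background,iur,rfc
Freon-12,regulated_CFC,120.91,102,0.75,12500,5,501,,
Freon-114,regulated_CFC,170.92,189,0.53,9450,3,16,,
Bromomethane,regulated_CFC,94.94,0.80,0.57,2,2,6.6,,0.005
Freon-11,regulated_CFC,137.37,52,1,6410,5,227,,
Freon-113,regulated_CFC,187.38,93,0.82,6530,3,71,,
Carbon tetrachloride,regulated_CFC,153.82,32,0.87,2150,4,78,6e-06,0.1
Chloromethane,unregulated_VSLS,50.49,0.90,0.02,6,17,493,,0.09
Methylene chloride,unregulated_VSLS,84.93,0.49,,11,15,49,1e-08,0.6
"1,1-Dichloroethane",unregulated_VSLS,98.96,0.37,,4,8,,1.6e-06,0.5
Chloroform,unregulated_VSLS,119.38,0.50,,20,6,9.8,2.3e-05,0.3
"1,2-Dichloroethane",unregulated_VSLS,98.96,0.23,,1,10,,2.6e-05,0.4
"1,2-Dichloropropane",unregulated_VSLS,112.99,0.07,,,9,,3.7e-06,0.004
Trichloroethylene,unregulated_VSLS,131.39,0.02,,,4,1.7,4.1e-06,0.002
Tetrachloroethylene,unregulated_VSLS,165.83,0.30,,6,4,3.3,2.6e-07,0.04
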
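name,mean,sd
Freon-12,563,20
Freon-114,17,4
Bromomethane,21,1
Freon-11,264,15
Freon-113,81,3
Carbon tetrachloride,92,9
Chloromethane,785,261
Methylene chloride,563,505
"1,1-Dichloroethane",73,47
Chloroform,64,39
"1,2-Dichloroethane",265,279
"1,2-Dichloropropane",67,37
Trichloroethylene,42,10
Tetrachloroethylene,27,15
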
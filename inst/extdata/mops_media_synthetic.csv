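name,base,lower,upper,solubility,fixed,unit
glucose,10,10,10,500,TRUE,g/L
MOPS,40,40,40,1000,TRUE,mM
Tricine,4,4,4,500,TRUE,mM
K2HPO4,1.32,0.33,13.2,3000,FALSE,mM
NaCl,50,5,500,5000,FALSE,mM
NH4Cl,9.52,0.952,95.2,5000,FALSE,mM
K2SO4,0.276,0.0276,2.76,500,FALSE,mM
FeSO4,0.01,0.001,0.1,100,FALSE,mM
MgCl2,0.523,0.0523,5.23,5000,FALSE,mM
Mo7O24,3e-06,3e-07,3e-05,1,FALSE,mM
H3BO3,4e-04,4e-05,0.004,100,FALSE,mM
CoCl2,3e-05,3e-06,3e-04,100,FALSE,mM
CuSO4,1e-05,1e-06,1e-04,100,FALSE,mM
MnSO4,8e-05,8e-06,8e-04,100,FALSE,mM
ZnSO4,1e-05,1e-06,1e-04,100,FALSE,mM
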
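atc2,class_name,atc5,inn,cases,noncases
A10,Drugs used in diabetes,,,28,35
A10,Drugs used in diabetes,A10BA02,metformin,12,20
A10,Drugs used in diabetes,A10BH01,sitagliptin,5,4
B01,Antithrombotic agents,,,34,62
B01,Antithrombotic agents,B01AE07,dabigatran etexilate,20,19
C03,Diuretics,,,12,20
C03,Diuretics,C03CA01,furosemide,5,4
C09,Agents acting on the renin-angiotensin system,,,25,39
C09,Agents acting on the renin-angiotensin system,C09CA03,valsartan,7,4
C10,Lipid modifying agents,,,11,24
C10,Lipid modifying agents,C10AA01,simvastatin,7,4
H02,Corticosteroids for systemic use,,,10,29
H02,Corticosteroids for systemic use,H02AB06,prednisolone,9,13
J01,Antibacterials for systemic use,,,36,140
J01,Antibacterials for systemic use,J01XA01,vancomycin,9,5
J02,Antimycotics for systemic use,,,8,16
J02,Antimycotics for systemic use,J02AA01,amphotericin B,5,12
J05,Antivirals for systemic use,,,121,178
J05,Antivirals for systemic use,J05AF07,tenofovir disoproxil,38,19
J05,Antivirals for systemic use,J05AF09,emtricitabine,24,13
J05,Antivirals for systemic use,J05AF13,tenofovir alafenamide,5,1
J05,Antivirals for systemic use,J05AG03,efavirenz,7,12
J05,Antivirals for systemic use,J05AP08,sofosbuvir,6,30
J05,Antivirals for systemic use,J05AP51,sofosbuvir and ledipasvir,6,28
L01,Antineoplastic agents,,,92,196
L01,Antineoplastic agents,L01EB02,erlotinib,6,6
L01,Antineoplastic agents,L01EG02,everolimus,9,0
L01,Antineoplastic agents,L01EX01,sunitinib,5,3
L04,Immunosuppressants,,,52,178
L04,Immunosuppressants,L04AA06,mycophenolic acid,9,8
L04,Immunosuppressants,L04AB04,adalimumab,9,27
L04,Immunosuppressants,L04AD01,ciclosporin,15,3
L04,Immunosuppressants,L04AD02,tacrolimus,5,5
V03,All other therapeutic products,,,9,3
V03,All other therapeutic products,V03AC03,deferasirox,9,0
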
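case	outcome	sex	karyotype	fish_major_clone	fish_pmc	karyotype_concordant
CR01	CR	M	58,XY,+X,-Y,+4,+6,+8,+10,+11,+12,+14,+17,+18,+21,+21,+22 (SNP6)	01110111	4.74	FALSE
CR02	CR	F	53,XX,+X,+X,+6,+14,+17,+21,+21 (SNP6)	10001102	7.95	FALSE
CR03	CR	M	55 XXYY,+4,+6,+12,+15,+18,+21	11111111	7.12	FALSE
CR04	CR	F	54,XX,+X,+6,+8,+14,+17,+18,+21,+21[15]/54,idem,-13,+mar[11]/46,XX[19]	10101102	7.39	FALSE
CR05	CR	F	57,XX,+X,+X,+4,+6,+8,+10,+14,+17,+18,+21,+21 (SNP6)	21111111	10.85	FALSE
CR06	CR	M	54,X,+X,Y,+6,+10,+14,+17,+18,+21,+mar[30]	10111111	12.95	TRUE
CR07	CR	M	55,XXY,+3,+4,+6,+10,+14,+18,+21,+21/46,XY	11111012	8	TRUE
CR08	CR	M	60,XY,+X,+4,+6,+7,+8,+9,+14,+17,+18,+21,+21,+3mar/46,XY	11112122	3.96	FALSE
CR09	CR	M	57,XXY,+4,+6,+8,+10,+10?,+13,+14,+17,+18,+21[14]/46,XY[16]	11121111	2.55	TRUE
CR10	CR	F	54,XXX,+4,+6,+8,inv(9)(p11q12),+14,+17,+18,+21[22]/46,XX,inv(9)(p11q12)[2]	11101111	7.72	TRUE
REL01	REL	M	59,XY,+?X,+4,+6,+7,+8,+12,+14,+?add(17)(p1),+18,+18,+21,+der(?)t(?;5)(?;q?13),+mar[6]/63,idem,dup(1)(q2q3),+22,inc[7]/46,XY[5]	11121121	3.61	FALSE
REL02	REL	F	51,XX,+X,+8,+14,+21,+21[5]/46,XX[9]	10001002	30.32	TRUE
REL03	REL	M	54,XY,+X,+4,+6,+10,+14,+add(19)(p13),+20,+21[cp8]	11111102	10.36	FALSE
REL04	REL	F	46,XX[20]/High hyperdiploid by FISH	01112002	22.3	FALSE
REL05	REL	M	52-56,XY,+X,dup(1)(q25q44),+4,+8,+10,+11,+14,+18,+21,+21,+mar[cp7]/46,XY[3]	11011002	9.09	FALSE
REL06	REL	M	46,XY[20]/High hyperdiploid by FISH	11111111	5.83	FALSE
REL07	REL	M	56,XY,+X,ins(1;?),(q21.3;?),+4,+6,+14,+17,+18,+21,+21,+22,+mar[5]/46,XY[5]	11101112	12	TRUE
REL08	REL	M	High hyperdiploid by FISH	10001002	11.57	FALSE
REL09	REL	F	51,XX,+X,+6,+14,+21,+21[16]/51,idem,add(9)(q34)[2]/46,XX[2]	10101002	10.85	TRUE
REL10	REL	F	53,XX,+4,+6,+14,+17,+18,+2mar[8]/46,XX[22]	11101111	7.86	FALSE
REL11	REL	M	59,XXY,+Y,der(1)(q?),+4,+5,+6,+8,+10,+11,+18,+18,+21,+22,mar[9]/46,XY[41]	12120022	8.45	FALSE
REL12	REL	M	57,XY,der(1)(p?q?),+4,10mar[56%]/46,XY[44%]	11121012	10.61	FALSE
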
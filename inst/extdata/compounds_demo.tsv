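name	formula	monoisotopic_mass
glycine	C2H5NO2	75.03203
alanine	C3H7NO2	89.04768
serine	C3H7NO3	105.04259
proline	C5H9NO2	115.06333
valine	C5H11NO2	117.07898
threonine	C4H9NO3	119.05824
leucine	C6H13NO2	131.09463
isoleucine	C6H13NO2	131.09463
asparagine	C4H8N2O3	132.05349
aspartate	C4H7NO4	133.03751
glutamine	C5H10N2O3	146.06914
glutamate	C5H9NO4	147.05316
lysine	C6H14N2O2	146.10553
methionine	C5H11NO2S	149.05105
histidine	C6H9N3O2	155.06948
phenylalanine	C9H11NO2	165.07898
arginine	C6H14N4O2	174.11168
tyrosine	C9H11NO3	181.07389
tryptophan	C11H12N2O2	204.08988
glucose	C6H12O6	180.06339
lactate	C3H6O3	90.03169
pyruvate	C3H4O3	88.01604
citrate	C6H8O7	192.02700
succinate	C4H6O4	118.02661
malate	C4H6O5	134.02152
fumarate	C4H4O4	116.01096
creatine	C4H9N3O2	131.06948
carnitine	C7H15NO3	161.10519
taurine	C2H7NO3S	125.01466
hypoxanthine	C5H4N4O	136.03851
inosine	C10H12N4O5	268.08077
adenosine	C10H13N5O4	267.09675
AMP	C10H14N5O7P	347.06308
NAD	C21H27N7O14P2	663.10912
acetylcarnitine	C9H17NO4	203.11576
palmitoylcarnitine	C23H45NO4	399.33486
oleoylcarnitine	C25H47NO4	425.35051
palmitate	C16H32O2	256.24023
stearate	C18H36O2	284.27153
oleate	C18H34O2	282.25588
linoleate	C18H32O2	280.24023
arachidonate	C20H32O2	304.24023
PC(34:1)	C42H82NO8P	759.57781
PC(36:2)	C44H84NO8P	785.59346
PE(34:2)	C39H74NO8P	715.51520
PE(36:4)	C41H74NO8P	739.51520
LPC(16:0)	C24H50NO7P	495.33249
Cer(d18:1/16:0)	C34H67NO3	537.51210
SM(d18:1/16:0)	C39H79N2O6P	702.56757
DAG(36:2)	C39H72O5	620.53798
TAG(52:2)	C55H102O6	858.76764
TAG(54:3)	C57H104O6	884.78329
CL(72:8)	C81H142O17P2	1448.97223
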
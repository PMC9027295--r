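Name	Q1	Q3	CE	Polarity	Formula	MS2Formula	MS2FormulaType	Tags
PC_34:2	758.57	184.07	33	Positive	C42H81O8NP	C5H15O4NP	ConstantProduct	PC
PC_34:1	760.59	184.07	33	Positive	C42H83O8NP	C5H15O4NP	ConstantProduct	PC
PC_34:0	762.60	184.07	33	Positive	C42H85O8NP	C5H15O4NP	ConstantProduct	PC
SM_38:1;O2	759.64	184.07	33	Positive	C43H88N2O6P	C5H15O4NP	ConstantProduct	SM
LPC_18:0	524.37	184.07	33	Positive	C26H55O7NP	C5H15O4NP	ConstantProduct	LPC
PS_34:2	758.50	671.47	45	Negative	C40H73O10NP	C3H5O2N	ConstantNeutralLoss	PS
PS_34:1	760.51	673.48	45	Negative	C40H75O10NP	C3H5O2N	ConstantNeutralLoss	PS
unknown_900	900.10	184.07		Positive				
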
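transcript	gene	mean	sd	cv	is_target
CL10201.Contig1_All	LbCYP	1142.214286	718.6318388	0.62915676	FALSE
CL1082.Contig3_All	LbTBP	138.5714286	38.5141618	0.27793725	FALSE
Unigene36249_All	LbGAPDH	145.4285714	68.28527748	0.46954513	FALSE
CL13903.Contig10_All	LbTUB	57.57142857	57.88412069	1.005431377	FALSE
CL2539.Contig4_All	LbEF1a	3196.071429	823.6067456	0.257693473	FALSE
CL4826.Contig3_All	LbActin7	626.5714286	191.7922411	0.306097968	FALSE
Unigene44516_All	LbHSP90	126.0714286	53.97501457	0.428130427	FALSE
CL13810.Contig1_All	LbHIS3	2307.928571	612.946536	0.265582975	FALSE
CL10058.Contig1_All	LbCYC	1009	92.22297394	0.091400371	FALSE
Unigene55248_All	LbEIF4A	2087.928571	165.8161467	0.07941658	FALSE
Unigene19346_All	LbPP2A	831.8571429	99.63923937	0.119779268	FALSE
CL11175.Contig21_All	LbUBQ	1211.428571	186.5371542	0.153981141	FALSE
Unigene15131_All	LbCML38	695	106.1066227	0.1526714	FALSE
CL7969.Contig1_All	LbLEA	525.7142857	113.3995174	0.215705604	FALSE
Unigene31075_All	LbEF1b	5663	1138.411849	0.201026285	FALSE
Unigene26461_All	LbSKIP	612.5	120.2361459	0.196303912	FALSE
Unigene55138_All	LbRH52	950.4285714	113.8816621	0.119821379	FALSE
Unigene59903_All	LbRPL7A	793.6428571	149.1166849	0.187888902	FALSE
Unigene59939_All	LbMYB1	2982.571429	697.3143085	0.233796348	TRUE
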
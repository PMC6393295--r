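id	ruleset	substrate	violations
PhtRNA-Thr-CGU	PhNSun6	TRUE	
PhtRNA-Thr-GGU	PhNSun6	TRUE	
PhtRNA-Thr-UGU	PhNSun6	TRUE	
PhtRNA-Cys-GCA	PhNSun6	TRUE	
PhtRNA-Ser-UGA	PhNSun6	TRUE	
PhtRNA-Ser-CGA	PhNSun6	TRUE	
PhtRNA-Ser-GGA	PhNSun6	TRUE	
PhtRNA-Ser-GCU	PhNSun6	TRUE	
PhtRNA-Asn-GUU	PhNSun6	TRUE	
PhtRNA-Asp-GUC	PhNSun6	TRUE	
PhtRNA-Arg-GCG	PhNSun6	TRUE	
PhtRNA-Phe-GAA	PhNSun6	FALSE	n73;pair_2_71
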
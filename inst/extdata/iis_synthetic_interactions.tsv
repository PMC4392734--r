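gene_a	gene_b	interaction_class	evidence_class	publications
daf-2	daf-16	physical	experimental	SPUB0001|SPUB0002|SPUB0003|SPUB0004|SPUB0005|SPUB0006|SPUB0007|SPUB0008|SPUB0009|SPUB0010|SPUB0011|SPUB0012|SPUB0013|SPUB0014|SPUB0015|SPUB0016|SPUB0017|SPUB0018|SPUB0019|SPUB0020|SPUB0021|SPUB0022|SPUB0023|SPUB0024|SPUB0025|SPUB0026|SPUB0027|SPUB0028|SPUB0029|SPUB0030|SPUB0031|SPUB0032|SPUB0033|SPUB0034|SPUB0035|SPUB0036|SPUB0037|SPUB0038|SPUB0039|SPUB0040|SPUB0041|SPUB0042|SPUB0043|SPUB0044|SPUB0045|SPUB0046|SPUB0047|SPUB0048|SPUB0049|SPUB0050|SPUB0051|SPUB0052|SPUB0053|SPUB0054|SPUB0055|SPUB0056|SPUB0057|SPUB0058|SPUB0059|SPUB0060|SPUB0061|SPUB0062|SPUB0063|SPUB0064|SPUB0065|SPUB0066|SPUB0067|SPUB0068|SPUB0069|SPUB0070|SPUB0071|SPUB0072|SPUB0073|SPUB0074|SPUB0075|SPUB0076|SPUB0077|SPUB0078|SPUB0079|SPUB0080|SPUB0081|SPUB0082|SPUB0083|SPUB0084|SPUB0085|SPUB0086|SPUB0087|SPUB0088|SPUB0089|SPUB0090|SPUB0091|SPUB0092|SPUB0093|SPUB0094|SPUB0095|SPUB0096|SPUB0097|SPUB0098|SPUB0099|SPUB0100|SPUB0101|SPUB0102|SPUB0103|SPUB0104|SPUB0105|SPUB0106|SPUB0107|SPUB0108|SPUB0109|SPUB0110|SPUB0111|SPUB0112|SPUB0113|SPUB0114|SPUB0115|SPUB0116|SPUB0117|SPUB0118|SPUB0119|SPUB0120|SPUB0121|SPUB0122|SPUB0123|SPUB0124|SPUB0125|SPUB0126|SPUB0127|SPUB0128|SPUB0129|SPUB0130|SPUB0131|SPUB0132|SPUB0133|SPUB0134|SPUB0135
daf-3	daf-16	genetic	experimental	SPUB0136
daf-2	daf-3	genetic	experimental	SPUB0137
peb-1	daf-16	genetic	experimental	SPUB0138
myo-2	daf-16	genetic	experimental	SPUB0139
daf-36	daf-16	genetic	experimental	SPUB0140
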
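metric	count
patients_total	204
patients_metastatic	15
aggressive_reviewed	12
dediff_patients	7
wes_patients	11
tp53_mutant_patients	7
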
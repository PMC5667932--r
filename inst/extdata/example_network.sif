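DUSP6	activates	PPTC7
PPTC7	activates	PTPN1
PPTC7	inhibits	DUSP6
PTPN1	activates	PTPN13
PTPN1	inhibits	PPTC7
PTPN13	activates	PPP3CA
PTPN13	activates	DUSP10
PTPN13	inhibits	PTPN1
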
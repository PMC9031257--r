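name	class	formula	acyls
DG(32:0)	DG	C35H68O5	16:0/16:0
DG(34:0)	DG	C37H72O5	16:0/18:0
DG(34:1)	DG	C37H70O5	16:0/18:1
DG(36:1)	DG	C39H74O5	18:0/18:1
DG(36:2)	DG	C39H72O5	18:1/18:1
DG(38:1)	DG	C41H78O5	18:0/20:1
TG(48:0)	TG	C51H98O6	16:0/16:0/16:0
TG(50:1)	TG	C53H100O6	16:0/16:0/18:1
TG(52:2)	TG	C55H102O6	16:0/18:1/18:1
TG(52:3)	TG	C55H100O6	16:1/18:1/18:1
TG(54:2)	TG	C57H106O6	18:0/18:1/18:1
TG(54:3)	TG	C57H104O6	18:1/18:1/18:1
PC(32:0)	PC	C40H80NO8P	16:0/16:0
PC(34:1)	PC	C42H82NO8P	16:0/18:1
PC(36:2)	PC	C44H84NO8P	18:1/18:1
PC(37:1)	PC	C45H88NO8P	17:0/20:1
PC(37:4)	PC	C45H82NO8P	17:1/20:3
PC(38:4)	PC	C46H84NO8P	18:0/20:4
PC(40:1)	PC	C48H94NO8P	18:0/22:1
SM(d34:1)	SM	C39H79N2O6P	
SM(d36:1)	SM	C41H83N2O6P	
SM(d38:1)	SM	C43H87N2O6P	
SM(d40:1)	SM	C45H91N2O6P	
SM(d42:2)	SM	C47H93N2O6P	
PA(34:1)	PA	C37H71O8P	16:0/18:1
PA(36:2)	PA	C39H73O8P	18:1/18:1
PA(36:1)	PA	C39H75O8P	18:0/18:1
CerPE(d34:1)	CerPE	C36H73N2O6P	
CerPE(d40:1)	CerPE	C42H85N2O6P	
CerPE(d42:2)	CerPE	C44H87N2O6P	
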
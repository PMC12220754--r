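verbatim	canonical
SINGULAIR	MONTELUKAST
MONTELUKAST	MONTELUKAST
MONTELUKAST SODIUM	MONTELUKAST
SINGULAIR (MONTELUKAST SODIUM)	MONTELUKAST
MONTELUKAST NA	MONTELUKAST
ASPIRIN	ASPIRIN
ACETYLSALICYLIC ACID	ASPIRIN
PARACETAMOL	PARACETAMOL
ACETAMINOPHEN	PARACETAMOL
TYLENOL	PARACETAMOL
IBUPROFEN	IBUPROFEN
ADVIL	IBUPROFEN
CETIRIZINE	CETIRIZINE
CETIRIZINE HYDROCHLORIDE	CETIRIZINE
ZYRTEC	CETIRIZINE
PREDNISONE	PREDNISONE
SALBUTAMOL	SALBUTAMOL
ALBUTEROL	SALBUTAMOL
VENTOLIN	SALBUTAMOL
FLUTICASONE	FLUTICASONE
FLUTICASONE PROPIONATE	FLUTICASONE
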
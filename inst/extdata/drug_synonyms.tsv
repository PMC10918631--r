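chembl_id	synonym
CHEMBL941	Imatinib
CHEMBL941	Gleevec
CHEMBL941	Glivec
CHEMBL941	STI-571
CHEMBL1201583	Trastuzumab
CHEMBL1201583	Herceptin
CHEMBL25	Aspirin
CHEMBL25	Acetylsalicylic Acid
CHEMBL1642	Sunitinib
CHEMBL1642	Sutent
CHEMBL553	Erlotinib
CHEMBL553	Tarceva
CHEMBL185	Fluorouracil
CHEMBL185	5-FU
CHEMBL88	Doxorubicin
CHEMBL88	Adriamycin
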
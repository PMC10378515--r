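symbol	diseases	product_class	tissue_class	association_strength	established_variants	multi_system
MTHFR	M607093|clotting diathesis|other|primary	enzyme	clotting	reported		FALSE
COL5A1	M130000|classical EDS|tissue_laxity|primary	structural	joint	established		FALSE
COL5A2	M130010|classical EDS|tissue_laxity|primary	structural	joint	established		FALSE
COL3A1	M130050|vascular EDS|tissue_laxity|primary	structural	cardiovascular	established		TRUE
COL1A1	M166200|osteogenesis imperfecta|tissue_laxity|primary	structural	bone	established		FALSE
FLG	M146700|ichthyosis vulgaris|other|primary;M135940|skin inflammation synergy in connective tissue dysplasia|tissue_laxity,immune_inflammatory|secondary	structural	skin	reported		FALSE
POLG	M203700|POLG-related developmental encephalopathy|neuro,developmental,mitochondrial|primary;M613662|POLG-related gastrointestinal dysmotility encephalopathy|autonomic,neuro,mitochondrial|primary	enzyme	neural	established		TRUE
HBB	M603903|sickle cell carrier status|other|primary	transport	cardiovascular	established	p.(Glu6Val)	FALSE
BRCA1	M113705|breast/ovarian cancer predisposition|other|primary	enzyme	developmental	established		FALSE
VWF	M193400|von Willebrand disease|clotting|primary	adhesion	clotting	established		FALSE
F2	M176930|prothrombin thrombophilia|clotting|primary	enzyme	clotting	established		FALSE
PIK3R1	M269880|SHORT syndrome|tissue_laxity,developmental|primary	signal	skin	reported		TRUE
SLC6A2	M604715|orthostatic intolerance|autonomic|primary	transport	autonomic_other	reported		FALSE
ADAMTS2	M225410|dermatosparaxis EDS|tissue_laxity|primary	enzyme	skin	established		FALSE
NLRP3	M191900|cryopyrin-associated periodic syndrome|immune_inflammatory|primary	signal	immune_inflammatory	established		FALSE
LIFR	M601559|Stuve-Wiedemann syndrome|developmental|primary	receptor	developmental	reported		FALSE
ACE2	M300335|coronavirus spike receptor, renal vascular expression|viral_response,renal_vascular|primary	enzyme	renal_vascular	reported		FALSE
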
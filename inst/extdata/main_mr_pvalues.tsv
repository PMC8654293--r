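biomarker	disease	p	published_fdr
CD40	Psoriasis	6.6e-3	1.8e-1
IL-12B	Psoriatic arthropathy	4.5e-6	3.4e-4
IL-12B	Psoriasis	2.7e-13	1.0e-10
IL-18R1	Asthma	1.6e-1	7.5e-1
IL-18R1	Eczema	7.0e-5	4.4e-3
IL-18R1	Hay fever	5.3e-4	2.8e-2
IL-18R1	Allergy	1.4e-3	4.8e-2
IL-18R1	Celiac disease	3.2e-3	1.0e-1
LAP-TGF-beta-1	Osteoarthritis	9.0e-4	3.4e-2
LT-alpha	Type 1 diabetes	2.4e-10	4.5e-8
LT-alpha	Rheumatoid arthritis	4.1e-6	3.4e-4
LT-alpha	Psoriasis	1.5e-2	2.9e-1
LT-alpha	Celiac disease	5.7e-9	7.1e-7
TWEAK	Asthma	6.0e-4	2.8e-2
VEGF-A	Ulcerative colitis	8.7e-4	3.4e-2
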
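# evlfq stage=standardized source=printed_candidate_table note=per-condition average abundances of the top 20 co-culture-elevated proteins
protein_id	gene_symbol	description	Average PSC	Average KPC	Average CoC
Cxcl2	Cxcl2	C-X-C motif chemokine 2	-0.54722	-0.77428	1.321498
Mmp3	Mmp3	MCG9886	-0.83013	-0.48459	1.314718
Cxcl1	Cxcl1	Growth-regulated alpha protein	-0.5383	-0.77518	1.313477
Sfrp2	Sfrp2	Secreted frizzled-related protein 2	-0.55275	-0.74882	1.301561
Kif5b	Kif5b	Kinesin-1 heavy chain	-0.68642	-0.60435	1.29077
Crip1	Crip1	Cysteine-rich protein 1	-0.47614	-0.79921	1.275346
Loxl2	Loxl2	Lysyl oxidase homolog 2	-0.77609	-0.46652	1.242616
Eef1g	Eef1g	Elongation factor 1-gamma	-0.41052	-0.81586	1.226383
Eif5a	Eif5a	Eukaryotic translation initiation factor 5A-1	-0.59361	-0.62604	1.219655
Slc9a3r1	Slc9a3r1	Na(+)/H(+) exchange regulatory cofactor NHE-RF1	-0.6843	-0.51219	1.196483
Glg1	Glg1	Golgi apparatus protein 1	-0.98063	-0.21264	1.193274
B2m	B2m	Beta-2-microglobulin	-1.01516	-0.16017	1.175321
Capg	Capg	Capping protein (Actin filament), gelsolin-like	-0.04136	-1.12458	1.165935
Impdh2	Impdh2	Inosine-5'-monophosphate dehydrogenase 2	-1.11283	-0.05005	1.162882
Hdgf	Hdgf	Hepatoma-derived growth factor	-1.02418	-0.12742	1.151603
Rbmxl1	Rbmxl1	RNA binding motif protein, X-linked-like-1	-0.60948	-0.53024	1.139722
Il6	Il6	Interleukin-6	-0.05663	-1.08047	1.137099
Aimp1	Aimp1	Aminoacyl tRNA synthase complex-interacting multifunctional protein 1	-0.44069	-0.6953	1.13599
Ccn3	Ccn3	Protein NOV homolog	0.04454	-1.1511	1.10656
Lgals4	Lgals4	Galectin-4	-0.11029	-0.97563	1.085925
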
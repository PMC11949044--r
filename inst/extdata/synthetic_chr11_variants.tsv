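#schema: symbol	variant_id	bp	cdna	protein	class	score
symbol	variant_id	bp	cdna	protein	class	score
Bptf	sv_bptf_1	107101200	c.3511delA	p.T1171fs	frameshift	NA
Ube2o	sv_ube2o_1	107331540	c.G1150A	p.V384I	missense	-1.0
Aanat	sv_aanat_1	107441260	c.C310T	p.R104X	nonsense	NA
Helz	sv_helz_1	107612400	c.1024+1G>A	NA	splice	NA
Tmc8	sv_tmc8_1	109761100	c.G505A	p.A169T	missense	-3.1
Tmc6	sv_tmc6_1	109781425	c.901_903del	p.301del	indel	-4.2
Syngr2	sv_syngr2_1	109803210	c.G122A	p.R41H	missense	-0.8
Tnrc6c	sv_tnrc6c_1	110051800	c.C2206T	p.Q736X	nonsense	NA
Map2k6	rs51129320	110490856	c.G227A	p.G76E	missense	-3.66
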
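#schema: symbol	chrom	start_bp	end_bp	aorta_expressed	differentially_expressed
symbol	chrom	start_bp	end_bp	aorta_expressed	differentially_expressed
Bptf	11	107040000	107140000	TRUE	TRUE
Ube2o	11	107310000	107370000	TRUE	FALSE
Aanat	11	107440000	107443000	FALSE	FALSE
Helz	11	107590000	107680000	TRUE	TRUE
Gprc5c	11	108570000	108590000	TRUE	FALSE
Rgs9	11	109160000	109250000	FALSE	FALSE
Grin2c	11	109690000	109710000	FALSE	FALSE
Tmc8	11	109750000	109768000	FALSE	FALSE
Tmc6	11	109770000	109790000	TRUE	FALSE
Syngr2	11	109800000	109806000	TRUE	FALSE
Tnrc6c	11	110020000	110090000	TRUE	FALSE
Map2k6	11	110370000	110500000	TRUE	TRUE
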
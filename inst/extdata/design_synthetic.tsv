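# Synthetic example design (not a real primer set).
# Degenerate 10-nt proximal consensus with exactly four concrete expansions,
# a 17-nt distal primer, and 12 inline 8-nt barcodes.
proximal_consensus	CAACGCGMRG
distal_primer	AGGTGGTGCATGGTTGT
proximal_window	40
distal_window	30
barcode	S01	AACTCGTC
barcode	S02	ACTAGCAG
barcode	S03	AGTCTGGA
barcode	S04	ATCGCAAC
barcode	S05	CAGTTGCA
barcode	S06	CGATACCA
barcode	S07	CTGAAGCT
barcode	S08	GACCTAAC
barcode	S09	GTTCAGAC
barcode	S10	TACGTCTG
barcode	S11	TGCAGTCA
barcode	S12	TTGGACGA
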
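lncrna_id	mirna_ids	mrna_ids
ENSMUST00000127786	miR-362-3p;miR-329-3p;miR-466i-3p;miR-669b-5p;miR-3057-5p;miR-5101;miR-15a-5p;miR-466o-3p;miR-466m-3p;miR-539-5p	Clec7a;5730455P16Rik;Fnbp1;Elovl2
MSTRG.17500.2	miR-362-3p;miR-329-3p;miR-466i-3p;miR-669b-5p;miR-3057-5p;miR-5101;miR-15a-5p;miR-466o-3p;miR-466m-3p;miR-539-5p	Clec7a;5730455P16Rik;Fnbp1;Elovl2
ENSMUST00000184170	miR-669b-5p;miR-15a-5p	5730455P16Rik;Fnbp1
MSTRG.1243.32	miR-362-3p;miR-329-3p;miR-466i-3p;miR-5101;miR-466o-3p;miR-466m-3p;miR-539-5p	Clec7a;5730455P16Rik;Fnbp1;Elovl2
MSTRG.16327.2	miR-3057-5p	5730455P16Rik
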
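# Approximate average 16S rRNA operon copy numbers per genome for genera
# discussed in the package documentation. Bundled defaults for worked
# examples only; for real analyses export current values from rrnDB.
genus	copy_number
Methanosarcina	3
Methanosaeta	2
Methanoculleus	2
Methanobacterium	2
Syntrophobacter	2
Syntrophomonas	3
Pelotomaculum	2
Desulfovibrio	4
Aminobacterium	2
Mesotoga	2
Thermovirga	2
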